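#' Construct a validated, topologically sorted pedigree
#'
#' A pedigree is an ordered set of (animal, sire, dam) triples. Construction
#' validates uniqueness of animal ids, resolves parent references, orders the
#' entries so every parent precedes its offspring, and rejects cyclic
#' pedigrees (an animal appearing among its own ancestors).
#'
#' @param animal,sire,dam character vectors of equal length; ids are opaque
#'   tokens and preserved verbatim. Unknown parents carry the sentinel code.
#' @param unknown sentinel value marking an unknown parent (default `"0"`).
#'   `NA` and the empty string are always treated as unknown too.
#' @param add_parents if `TRUE`, a parent id that does not occur among the
#'   animal ids is appended as a founder; if `FALSE` (default) this is an
#'   error.
#' @return An object of class `pedigree`: a list with `id` (character, in
#'   topological order), and `sire`/`dam` (integer positions into `id`, `0L`
#'   for unknown).
#' @export
pedigree <- function(animal, sire, dam, unknown = "0", add_parents = FALSE) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  stopifnot(length(sire) == length(animal), length(dam) == length(animal))
  if (anyDuplicated(animal)) {
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  is_unknown <- function(x) is.na(x) | x == unknown | x == ""
  sire[is_unknown(sire)] <- NA_character_
  dam[is_unknown(dam)] <- NA_character_

  parents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(parents)) {
    if (!add_parents) {
      stop("parent id(s) not present as animals: ",
           paste(head(parents, 5L), collapse = ", "),
           if (length(parents) > 5L) ", ..." else "",
           " (use add_parents = TRUE to append them as founders)")
    }
    animal <- c(animal, parents)
    sire <- c(sire, rep(NA_character_, length(parents)))
    dam <- c(dam, rep(NA_character_, length(parents)))
  }

  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)

  # Kahn's algorithm on parent -> offspring edges; leftover nodes mean a cycle
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(head(animal[setdiff(seq_len(n), order)], 5L), collapse = ", "))
  }

  pos <- integer(n); pos[order] <- seq_len(n)
  remap <- function(ix) ifelse(is.na(ix), 0L, pos[ix])
  structure(
    list(id = animal[order],
         sire = as.integer(remap(si)[order]),
         dam = as.integer(remap(di)[order])),
    class = "pedigree")
}

#' Read a pedigree file
#'
#' Reads a delimited three-column table (animal, sire, dam); the delimiter
#' (comma, tab or whitespace) is auto-detected and a header line is skipped
#' if its first field looks like a column name rather than an id shared with
#' the data.
#'
#' @param path path to the pedigree file.
#' @inheritParams pedigree
#' @return a [pedigree] object.
#' @export
read_pedigree <- function(path, unknown = "0", add_parents = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  dat <- read.table(path, sep = sep, header = FALSE,
                    colClasses = "character", strip.white = TRUE,
                    blank.lines.skip = TRUE)
  if (ncol(dat) < 3L) stop("pedigree file must have 3 columns (animal, sire, dam)")
  if (tolower(dat[1L, 1L]) %in% c("animal", "id", "animal_id")) dat <- dat[-1L, , drop = FALSE]
  pedigree(dat[[1L]], dat[[2L]], dat[[3L]], unknown = unknown,
           add_parents = add_parents)
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(x$sire == 0L & x$dam == 0L)
  cat(sprintf("pedigree: %d animals (%d founders), topologically sorted\n",
              length(x$id), nf))
  invisible(x)
}

#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(animal = x$id,
             sire = ifelse(x$sire == 0L, NA_character_, x$id[pmax(x$sire, 1L)]),
             dam = ifelse(x$dam == 0L, NA_character_, x$id[pmax(x$dam, 1L)]),
             stringsAsFactors = FALSE)
}

n_animals <- function(ped) length(ped$id)

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes each animal's inbreeding coefficient F (half the additive
#' relationship of its parents) by tracing the generalized Cholesky rows of
#' the relationship matrix upward through the pedigree, so no dense matrix is
#' formed. Unknown parents are treated as unrelated base-population founders.
#'
#' @param ped a [pedigree].
#' @return named numeric vector of F in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(is(ped, "pedigree"))
  f <- cpp_inbreeding(ped$sire, ped$dam)
  names(f) <- ped$id
  f
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the dense additive relationship matrix A by the recursive tabular
#' method: for ordered animals, `a(i,j) = (a(j,s_i) + a(j,d_i))/2` for `j < i`
#' and `a(i,i) = 1 + a(s_i,d_i)/2`, unknown parents contributing zero.
#'
#' Dense storage grows quadratically; pedigrees beyond `max_animals` are
#' refused, and the sparse [inverse_relationship()] should be used instead
#' (the sampler only ever needs the inverse).
#'
#' @param ped a [pedigree].
#' @param max_animals guard against accidental huge dense allocations.
#' @return dense symmetric matrix with dimnames = animal ids.
#' @export
relationship_matrix <- function(ped, max_animals = 5000L) {
  stopifnot(is(ped, "pedigree"))
  n <- n_animals(ped)
  if (n > max_animals) {
    stop("pedigree has ", n, " animals; dense A refused beyond ", max_animals,
         " (use inverse_relationship() instead)")
  }
  A <- matrix(0, n, n)
  s <- ped$sire; d <- ped$dam
  for (i in seq_len(n)) {
    rs <- if (s[i] > 0L) A[s[i], seq_len(i - 1L)] else numeric(i - 1L)
    rd <- if (d[i] > 0L) A[d[i], seq_len(i - 1L)] else numeric(i - 1L)
    if (i > 1L) {
      row <- 0.5 * (rs + rd)
      A[i, seq_len(i - 1L)] <- row
      A[seq_len(i - 1L), i] <- row
    }
    asd <- if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# Mendelian sampling variance coefficients given parental inbreeding:
# both parents known 0.5 - (F_s + F_d)/4; one known 0.75 - F_known/4; none 1.
mendelian_variance <- function(ped, f = inbreeding(ped)) {
  s <- ped$sire; d <- ped$dam
  fs <- ifelse(s > 0L, f[pmax(s, 1L)], -1)   # F = -1 encodes "unknown" below
  fd <- ifelse(d > 0L, f[pmax(d, 1L)], -1)
  # 0.5 - 0.25*Fs - 0.25*Fd with F(unknown) := -1 reproduces all three cases
  unname(0.5 - 0.25 * fs - 0.25 * fd)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by Henderson's rules,
#' accounting for inbreeding through the Mendelian sampling variances
#' computed from [inbreeding()]. Never forms dense A.
#'
#' @param ped a [pedigree].
#' @return a symmetric sparse `Matrix::dsCMatrix` with dimnames = animal ids.
#' @export
inverse_relationship <- function(ped) {
  stopifnot(is(ped, "pedigree"))
  n <- n_animals(ped)
  alpha <- 1 / mendelian_variance(ped)
  s <- ped$sire; d <- ped$dam
  i0 <- seq_len(n)

  ii <- i0; jj <- i0; xx <- alpha                       # offspring diagonal
  for (p in list(s, d)) {
    k <- which(p > 0L)
    ii <- c(ii, k, p[k])                                # offspring-parent
    jj <- c(jj, p[k], k)
    xx <- c(xx, rep(-alpha[k] / 2, 2L))
    ii <- c(ii, p[k]); jj <- c(jj, p[k])                # parent diagonal
    xx <- c(xx, alpha[k] / 4)
  }
  k <- which(s > 0L & d > 0L)                           # sire-dam cross terms
  ii <- c(ii, s[k], d[k]); jj <- c(jj, d[k], s[k])
  xx <- c(xx, rep(alpha[k] / 4, 2L))

  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  methods::as(Matrix::forceSymmetric(Ainv), "CsparseMatrix")
}
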