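#' Model specification for the three-trait analysis
#'
#' Fixes the trait order (WW, WY, AC) used throughout `G0`/`R0` indexing and
#' declares each trait's fixed effects: a contemporary-group factor for all
#' three traits, plus the age at measurement (months) as a linear covariate
#' for the two weights. The ordinal trait is scored in `n_categories`
#' classes cut by `n_categories - 1` fixed thresholds on the liability
#' scale.
#'
#' Both thresholds of the default 3-class trait are fixed (0 and 1) and the
#' liability residual variance is estimated instead: with all thresholds
#' fixed the threshold model is identified with a free residual variance,
#' which is the parameterization under which a non-unit AC residual variance
#' is reportable.
#'
#' @param center_age centre the age covariates at their sample means
#'   (default `TRUE`; affects only the intercept-like CG solutions, not
#'   variance components).
#' @param ac_covariate name of a numeric column to fit as a covariate for
#'   the ordinal trait, or `NULL` (default) for contemporary group only.
#' @param n_categories number of ordinal classes (default 3).
#' @param thresholds liability cutpoints, length `n_categories - 1`,
#'   strictly increasing; default `c(0, 1)`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(center_age = TRUE, ac_covariate = NULL,
                       n_categories = 3L, thresholds = c(0, 1)) {
  stopifnot(n_categories >= 2L, length(thresholds) == n_categories - 1L,
            !is.unsorted(thresholds, strictly = TRUE))
  structure(list(traits = c("ww", "wy", "ac"),
                 center_age = center_age,
                 ac_covariate = ac_covariate,
                 n_categories = as.integer(n_categories),
                 thresholds = thresholds),
            class = "model_spec")
}

# cell-means CG indicators plus optional covariate columns; errors on empty
# CG levels and on rank deficiency (e.g. a covariate constant everywhere)
trait_design <- function(records, cg_col, covariates, trait) {
  cg <- factor(as.character(records[[cg_col]]))
  if (any(table(cg) == 0L)) stop("contemporary group level with zero records")
  # cell-means indicators built directly (model.matrix rejects single-level
  # factors, which are legitimate here)
  X <- matrix(vapply(levels(cg), function(l) as.numeric(cg == l),
                     numeric(length(cg))),
              nrow = length(cg),
              dimnames = list(NULL, paste0(trait, ":cg", levels(cg))))
  for (cv in covariates) {
    if (is.null(records[[cv]])) stop("missing covariate column '", cv, "'")
    X <- cbind(X, records[[cv]])
    colnames(X)[ncol(X)] <- paste0(trait, ":", cv)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient fixed-effect structure for trait '", trait,
         "' (covariate collinear with contemporary groups?)")
  }
  X
}

#' Build the fixed-effect and genetic incidence structures
#'
#' Constructs, per trait, the fixed-effect matrix `X` (contemporary group in
#' cell-means coding, no intercept, plus the trait's covariates) and the
#' record-to-pedigree mapping `Z`. All pedigree animals carry a breeding
#' value whether phenotyped or not. The observation matrix `y` holds the two
#' weights; the ordinal trait enters as the class vector, its continuous
#' liability being latent.
#'
#' @param records prepared records (see [prepare_records()]): columns
#'   `animal`, `ww`, `wy`, `age_ww`, `age_wy`, `cg_ww`, `cg_wy`, `cg_ac`,
#'   `ac_class`.
#' @param ped a [pedigree] containing every phenotyped animal.
#' @param spec a [model_spec].
#' @return object of class `btlam_design`: list with `y` (n x 3, liability
#'   column `NA`), `ac_class`, `X` (list of per-trait matrices), `zi`
#'   (record to pedigree position), `latent`/`lower`/`upper` augmentation
#'   masks and bounds, and bookkeeping fields.
#' @export
build_design <- function(records, ped, spec = model_spec()) {
  stopifnot(is(ped, "pedigree"))
  n <- nrow(records)
  if (n == 0L) stop("no records")
  zi <- match(records$animal, ped$id)
  if (anyNA(zi)) {
    stop("phenotyped animal(s) absent from pedigree: ",
         paste(head(records$animal[is.na(zi)], 5L), collapse = ", "))
  }

  rec <- records
  if (spec$center_age) {
    rec$age_ww <- rec$age_ww - mean(rec$age_ww, na.rm = TRUE)
    rec$age_wy <- rec$age_wy - mean(rec$age_wy, na.rm = TRUE)
  }
  X <- list(
    ww = trait_design(rec, "cg_ww", "age_ww", "ww"),
    wy = trait_design(rec, "cg_wy", "age_wy", "wy"),
    ac = trait_design(rec, "cg_ac", spec$ac_covariate, "ac"))

  y <- cbind(ww = as.numeric(records$ww),
             wy = as.numeric(records$wy),
             ac = rep(NA_real_, n))
  ac_class <- records$ac_class
  if (is.null(ac_class)) ac_class <- rep(NA_integer_, n)
  stopifnot(all(is.na(ac_class) | (ac_class >= 1L & ac_class <= spec$n_categories)))

  # augmentation masks: the liability column is always latent; a missing
  # weight is latent and unconstrained
  latent <- cbind(is.na(y[, 1L]), is.na(y[, 2L]), rep(TRUE, n))
  tt <- c(-Inf, spec$thresholds, Inf)
  lower <- matrix(-Inf, n, 3L)
  upper <- matrix(Inf, n, 3L)
  known <- !is.na(ac_class)
  lower[known, 3L] <- tt[ac_class[known]]
  upper[known, 3L] <- tt[ac_class[known] + 1L]

  structure(list(y = y, ac_class = ac_class, X = X, zi = zi,
                 latent = latent, lower = lower, upper = upper,
                 n = n, q = n_animals(ped), animal_ids = ped$id,
                 record_animals = records$animal, spec = spec),
            class = "btlam_design")
}

#' @export
print.btlam_design <- function(x, ...) {
  p <- vapply(x$X, ncol, integer(1))
  cat(sprintf("btlam_design: %d records, %d pedigree animals\n", x$n, x$q))
  cat(sprintf("  fixed effects: ww %d, wy %d, ac %d columns (%d location parameters total)\n",
              p[1], p[2], p[3], n_location(x)))
  invisible(x)
}

#' Total number of location parameters (fixed effects + animal effects)
#' @param design a `btlam_design`.
#' @export
n_location <- function(design) {
  sum(vapply(design$X, ncol, integer(1))) + 3L * design$q
}

# flattened column-wise incidence encoding consumed by the C++ sweep
design_encoding <- function(design) {
  fpar_trait <- integer(0); fptr <- 0L
  frows <- integer(0); fvals <- numeric(0)
  for (t in seq_along(design$X)) {
    Xt <- design$X[[t]]
    for (j in seq_len(ncol(Xt))) {
      nz <- which(Xt[, j] != 0)
      fpar_trait <- c(fpar_trait, t - 1L)
      fptr <- c(fptr, fptr[length(fptr)] + length(nz))
      frows <- c(frows, nz - 1L)
      fvals <- c(fvals, Xt[nz, j])
    }
  }
  o <- order(design$zi)
  anim_rows <- (seq_len(design$n) - 1L)[o]
  cnt <- tabulate(design$zi, nbins = design$q)
  anim_ptr <- c(0L, cumsum(cnt))
  list(fpar_trait = fpar_trait, fpar_ptr = as.integer(fptr),
       frows = as.integer(frows), fvals = fvals,
       anim_ptr = as.integer(anim_ptr), anim_rows = as.integer(anim_rows))
}
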