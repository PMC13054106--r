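#' Posterior-mean breeding values
#'
#' Extracts the running posterior means of the animal effects accumulated
#' over retained cycles, one row per pedigree animal, together with each
#' animal's count of recorded progeny ("offspring in production": progeny
#' with at least one phenotype record in the analyzed dataset) and a sire
#' flag (appears as a sire in the pedigree).
#'
#' @param samples a `btlam_samples` run with `store_location = TRUE`.
#' @param ped the [pedigree] the chain was run on.
#' @param records the analyzed records (used for progeny counts); if `NULL`
#'   all pedigree progeny are counted.
#' @return data frame: `animal`, `ebv_ww` (kg), `ebv_wy` (kg), `ebv_ac`
#'   (liability units), `n_progeny`, `is_sire`.
#' @export
posterior_mean_ebv <- function(samples, ped, records = NULL) {
  a <- samples$a_mean
  stopifnot(nrow(a) == n_animals(ped))
  q <- n_animals(ped)
  child <- if (is.null(records)) seq_len(q) else
    unique(match(records$animal, ped$id))
  child <- child[!is.na(child)]
  n_prog <- tabulate(ped$sire[child], nbins = q) +
    tabulate(ped$dam[child], nbins = q)
  data.frame(animal = ped$id,
             ebv_ww = unname(a[, 1L]), ebv_wy = unname(a[, 2L]),
             ebv_ac = unname(a[, 3L]),
             n_progeny = n_prog,
             is_sire = seq_len(q) %in% ped$sire,
             stringsAsFactors = FALSE)
}

#' Subset sires by progeny count
#'
#' @param ebvs result of [posterior_mean_ebv()].
#' @param min_progeny minimum recorded progeny (10 for the strict subset, 1
#'   for "all sires with progeny").
#' @return the filtered EBV table (sires only).
#' @export
sire_subset <- function(ebvs, min_progeny = 1L) {
  out <- ebvs[ebvs$is_sire & ebvs$n_progeny >= min_progeny, , drop = FALSE]
  if (nrow(out) == 0L) warning("no sires with >= ", min_progeny, " progeny")
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; invariant to strictly
#' monotone transforms of either argument.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return the correlation.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (var(rank(x)) == 0 || var(rank(y)) == 0) {
    stop("zero rank variance: Spearman correlation undefined")
  }
  cor(x, y, method = "spearman")
}

#' Sire re-ranking report: Spearman correlations between trait EBVs
#'
#' Builds the standard two-subset report: pairwise Spearman correlations of
#' sire EBVs among sires with at least `min_strict` recorded progeny (upper
#' triangle) and among all sires with progeny (lower triangle), with the
#' per-trait mean, SD and median of the strict subset's EBVs.
#'
#' @param ebvs result of [posterior_mean_ebv()].
#' @param min_strict progeny threshold for the strict subset (default 10).
#' @return list: `matrix` (correlations; upper = strict subset, lower = all
#'   sires, diagonal 1), `n_strict`, `n_all`, `summary` (mean/SD/median per
#'   trait, strict subset).
#' @export
ebv_spearman <- function(ebvs, min_strict = 10L) {
  strict <- sire_subset(ebvs, min_strict)
  all <- sire_subset(ebvs, 1L)
  traits <- c("ww", "wy", "ac")
  cols <- paste0("ebv_", traits)
  M <- diag(3)
  dimnames(M) <- list(traits, traits)
  for (i in 1:2) for (j in (i + 1):3) {
    M[i, j] <- if (nrow(strict) >= 3L)
      spearman_cor(strict[[cols[i]]], strict[[cols[j]]]) else NA_real_
    M[j, i] <- if (nrow(all) >= 3L)
      spearman_cor(all[[cols[i]]], all[[cols[j]]]) else NA_real_
  }
  summ <- data.frame(
    trait = traits,
    mean = vapply(cols, function(cl) mean(strict[[cl]]), numeric(1)),
    sd = vapply(cols, function(cl) sd(strict[[cl]]), numeric(1)),
    median = vapply(cols, function(cl) stats::median(strict[[cl]]), numeric(1)),
    row.names = NULL)
  list(matrix = M, n_strict = nrow(strict), n_all = nrow(all),
       summary = summ)
}

#' Write the EBV table and Spearman report
#' @param ebvs result of [posterior_mean_ebv()].
#' @param report result of [ebv_spearman()] (optional).
#' @param dir output directory.
#' @export
write_ebv_report <- function(ebvs, report = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(ebvs, file.path(dir, "ebv.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(report)) {
    jsonlite::write_json(
      list(spearman = as.data.frame(report$matrix),
           n_strict = report$n_strict, n_all = report$n_all,
           summary = report$summary),
      file.path(dir, "spearman.json"),
      dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}
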