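#' Score the age-at-conception class
#'
#' Maps a pregnancy-diagnosis outcome and the female's age when the positive
#' diagnosis was recorded to the 3-point ordinal scale used for the
#' age-at-conception (AC) trait: negative diagnosis scores 1; a positive
#' diagnosis over 18 months scores 2; a positive diagnosis up to (and
#' including) 18 months scores 3, the precocious class.
#'
#' @param preg_positive logical vector; `TRUE` for a positive diagnosis.
#' @param age_at_diagnosis age in months at the positive diagnosis; may be
#'   `NA` for negative records.
#' @return integer vector of classes in `{1, 2, 3}`.
#' @export
assign_conception_class <- function(preg_positive, age_at_diagnosis) {
  preg_positive <- as.logical(preg_positive)
  if (any(preg_positive & is.na(age_at_diagnosis))) {
    stop("positive pregnancy diagnosis with missing age at diagnosis")
  }
  cls <- rep(1L, length(preg_positive))
  cls[preg_positive & age_at_diagnosis <= 18] <- 3L
  cls[preg_positive & age_at_diagnosis > 18] <- 2L
  cls
}

#' Remove outlying weight records
#'
#' Drops records whose trait value lies more than `k` standard deviations
#' from the mean, where mean and SD are computed once on the input set
#' (single pass, not iterated). The boundary is strict: a value at exactly
#' `mean + k * SD` is retained. If the SD is zero or undefined nothing is
#' removed. Records with a missing trait value are retained.
#'
#' @param records data frame of phenotype records.
#' @param trait `"ww"` or `"wy"` (the column screened).
#' @param k SD multiple (default 3).
#' @return the filtered data frame.
#' @export
filter_outliers <- function(records, trait = c("ww", "wy"), k = 3) {
  trait <- match.arg(trait)
  x <- records[[trait]]
  if (sum(!is.na(x)) < 2L) return(records)
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(records)
  drop <- !is.na(x) & abs(x - m) > k * s
  records[!drop, , drop = FALSE]
}

#' Build contemporary groups and drop undersized ones
#'
#' The contemporary group for a weight trait is the year+month of its
#' measurement (the `date_ww` / `date_wy` column, format `YYYY-MM`). Groups
#' holding fewer than `min_size` records are excluded together with their
#' records. The group label is written to a `cg_<trait>` column.
#'
#' @inheritParams filter_outliers
#' @param min_size minimum records per group (default 3, i.e. groups with
#'   more than two animals are kept).
#' @return the filtered data frame with a `cg_<trait>` column added.
#' @export
make_contemporary_groups <- function(records, trait = c("ww", "wy"),
                                     min_size = 3L) {
  trait <- match.arg(trait)
  datecol <- paste0("date_", trait)
  if (is.null(records[[datecol]])) stop("missing column '", datecol, "'")
  if (nrow(records) == 0L) {
    records[[paste0("cg_", trait)]] <- character(0)
    return(records)
  }
  dates <- as.character(records[[datecol]])
  if (anyNA(dates)) stop("missing ", datecol, " value(s)")
  label <- gsub("[^0-9]", "", dates)   # concatenated year+month, e.g. 201905
  records[[paste0("cg_", trait)]] <- label
  keep <- label %in% names(which(table(label) >= min_size))
  records[keep, , drop = FALSE]
}

#' Drop records of sires with too few recorded progeny
#'
#' Counts, for each known sire, its progeny among the records currently in
#' the dataset, and removes the records of sires with fewer than
#' `min_progeny`. Applied once (not iterated to a fixed point). Records whose
#' sire is unknown are retained: the rule targets sires.
#'
#' @inheritParams filter_outliers
#' @param ped a [pedigree] resolving each record's sire.
#' @param min_progeny minimum recorded progeny per sire (default 3).
#' @return the filtered data frame.
#' @export
filter_sire_progeny <- function(records, ped, min_progeny = 3L) {
  if (nrow(records) == 0L) return(records)
  pos <- match(records$animal, ped$id)
  if (anyNA(pos)) {
    stop("record animal(s) absent from pedigree: ",
         paste(head(records$animal[is.na(pos)], 5L), collapse = ", "))
  }
  sire <- ped$sire[pos]                     # 0 = unknown
  counts <- table(sire[sire > 0L])
  small <- as.integer(names(counts)[counts < min_progeny])
  records[!(sire %in% small), , drop = FALSE]
}

#' Class frequency table for the ordinal trait
#'
#' Absolute and percentage frequencies of the age-at-conception classes, with
#' the mean and SD of the age at diagnosis within each class. Percentages are
#' rounded to 2 decimals.
#'
#' @param records data frame with `ac_class` (and optionally `age_diag`).
#' @return data frame with columns `class`, `n`, `pct`, `age_mean`, `age_sd`.
#' @export
class_frequencies <- function(records) {
  cls <- records$ac_class
  stopifnot(!is.null(cls))
  lev <- sort(unique(cls))
  n <- vapply(lev, function(k) sum(cls == k), integer(1))
  age <- records$age_diag
  out <- data.frame(
    class = lev,
    n = n,
    pct = round(100 * n / sum(n), 2),
    age_mean = if (is.null(age)) NA_real_ else
      vapply(lev, function(k) mean(age[cls == k], na.rm = TRUE), numeric(1)),
    age_sd = if (is.null(age)) NA_real_ else
      vapply(lev, function(k) sd(age[cls == k], na.rm = TRUE), numeric(1)))
  rownames(out) <- NULL
  out
}

#' Run the full data-preparation pipeline
#'
#' Applies, in this order: AC class scoring, the 3-SD outlier screen on each
#' weight, contemporary-group construction (dropping groups under
#' `min_cg`), and the sire progeny filter. A record failing any stage is
#' dropped as a whole row, so the surviving set is complete across traits.
#' Stage-by-stage record counts are attached as attribute `"log"` and
#' optionally printed.
#'
#' @param records raw phenotype data frame (columns `animal`, `ww`, `age_ww`,
#'   `date_ww`, `wy`, `age_wy`, `date_wy`, `preg`, `age_diag`).
#' @param ped a [pedigree].
#' @param min_cg minimum contemporary-group size.
#' @param min_progeny minimum recorded progeny per sire.
#' @param sd_limit SD multiple for the outlier screen.
#' @param verbose print the stage log.
#' @return filtered data frame with `ac_class`, `cg_ww`, `cg_wy`, `cg_ac`
#'   columns; attribute `"log"` holds the stage report.
#' @export
prepare_records <- function(records, ped, min_cg = 3L, min_progeny = 3L,
                            sd_limit = 3, verbose = FALSE) {
  log <- data.frame(stage = "input", records = nrow(records))
  note <- function(stage, r) rbind(log, data.frame(stage = stage, records = nrow(r)))

  if (is.null(records$ac_class) && !is.null(records$preg)) {
    records$ac_class <- assign_conception_class(records$preg, records$age_diag)
  }
  records <- filter_outliers(records, "ww", k = sd_limit)
  log <- note("outliers_ww", records)
  records <- filter_outliers(records, "wy", k = sd_limit)
  log <- note("outliers_wy", records)
  records <- make_contemporary_groups(records, "ww", min_size = min_cg)
  log <- note("cg_ww", records)
  records <- make_contemporary_groups(records, "wy", min_size = min_cg)
  log <- note("cg_wy", records)
  records <- filter_sire_progeny(records, ped, min_progeny = min_progeny)
  log <- note("sire_progeny", records)

  # the ordinal trait has no measurement date of its own; it shares the
  # yearling contemporary group (both are near-yearling observations)
  if (is.null(records$cg_ac)) records$cg_ac <- records$cg_wy

  attr(records, "log") <- log
  if (verbose) {
    for (i in seq_len(nrow(log))) {
      message(sprintf("%-14s %6d records", log$stage[i], log$records[i]))
    }
  }
  records
}

#' Read a phenotype file
#'
#' Delimited text with named columns `animal`, `ww`, `age_ww`, `date_ww`,
#' `wy`, `age_wy`, `date_wy`, `preg`, `age_diag`; dates as `YYYY-MM`.
#'
#' @param path file path; comma- or tab-delimited, header required.
#' @return data frame of raw records.
#' @export
read_phenotypes <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else "\t"
  dat <- read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("animal", "ww", "age_ww", "date_ww", "wy", "age_wy", "date_wy")
  miss <- setdiff(need, names(dat))
  if (length(miss)) stop("phenotype file lacks column(s): ",
                         paste(miss, collapse = ", "))
  dat$animal <- as.character(dat$animal)
  if (!is.null(dat$preg)) dat$preg <- as.logical(dat$preg)
  dat
}
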