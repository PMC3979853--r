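#' Survey datasets of repeated transect counts
#'
#' A `survey_dataset` bundles the three tables produced by a repeated
#' line-transect monitoring scheme for singing males:
#'
#' * `counts`: one row per transect x year x visit with the number of
#'   singing males recorded (`NA` marks a visit that was scheduled but not
#'   carried out);
#' * `site_covariates`: one row per transect x year holding the proportion of
#'   the transect falling in each of four vegetation-height, four water-depth
#'   and four litter-cover categories (columns `veg1..veg4`, `water1..water4`,
#'   `litter1..litter4`); each block of four sums to 1;
#' * `obs_covariates`: one row per transect x year x visit with the
#'   visit-level conditions `rain_mm` (total daily precipitation),
#'   `temp_c` (mean daily temperature), `wind` (mean daily wind speed) and
#'   `day_of_season` (integer day since the start of the survey window).
#'
#' Rows are stored in canonical order (transect, then year, then visit), so
#' two datasets with the same content compare identical regardless of the
#' row order they were supplied in.  Every transect-year present in `counts`
#' must have exactly `J` visit rows (`J` = number of visits per site, usually
#' 3) and matching covariate rows.
#'
#' @param counts data frame with columns `transect`, `year`, `visit`, `count`.
#' @param site_covariates data frame with columns `transect`, `year` and the
#'   twelve category-proportion columns described above.
#' @param obs_covariates data frame with columns `transect`, `year`, `visit`,
#'   `rain_mm`, `temp_c`, `wind`, `day_of_season`.
#' @return An object of class `survey_dataset`: a list with elements
#'   `counts`, `site_covariates`, `obs_covariates`, `years` (sorted unique
#'   year labels) and `J` (visits per site-year).
#' @examples
#' counts <- data.frame(transect = 1, year = 2011, visit = 1:3, count = c(2, 3, 1))
#' site <- data.frame(transect = 1, year = 2011,
#'                    veg1 = 0.2, veg2 = 0.4, veg3 = 0.4, veg4 = 0,
#'                    water1 = 0, water2 = 0.6, water3 = 0.4, water4 = 0,
#'                    litter1 = 0.2, litter2 = 0.2, litter3 = 0.2, litter4 = 0.4)
#' obs <- data.frame(transect = 1, year = 2011, visit = 1:3,
#'                   rain_mm = c(0, 2.5, 0), temp_c = c(14, 16, 15),
#'                   wind = c(2, 3, 1), day_of_season = c(3, 5, 7))
#' survey_dataset(counts, site, obs)
#' @seealso [read_survey_dataset()], [write_survey_dataset()], [simulate_survey()]
#' @export
survey_dataset <- function(counts, site_covariates, obs_covariates) {
  check_columns(counts, c("transect", "year", "visit", "count"), "counts")
  check_columns(site_covariates, c("transect", "year", site_cov_columns()),
                "site_covariates")
  check_columns(obs_covariates,
                c("transect", "year", "visit", "rain_mm", "temp_c", "wind",
                  "day_of_season"), "obs_covariates")

  counts <- canonical_order(counts, c("transect", "year", "visit"))
  site_covariates <- canonical_order(site_covariates, c("transect", "year"))
  obs_covariates <- canonical_order(obs_covariates,
                                    c("transect", "year", "visit"))

  bad <- which(!is.na(counts$count) &
                 (counts$count < 0 | counts$count != round(counts$count)))
  if (length(bad))
    stop("counts must be non-negative integers (or NA for a missed visit); ",
         "offending row(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  counts$count <- as.integer(round(counts$count))

  visits <- sort(unique(counts$visit))
  J <- length(visits)
  if (!identical(as.integer(visits), seq_len(J)))
    stop("visits must be labelled 1..J; found: ",
         paste(visits, collapse = ", "), call. = FALSE)

  key_it <- function(d) paste(d$transect, d$year, sep = "\r")
  site_years <- unique(key_it(counts))
  tab <- table(key_it(counts))
  if (any(tab != J))
    stop("every transect-year must have exactly J = ", J, " visit rows ",
         "(use NA counts for missed visits); offending transect-year(s): ",
         paste(head(gsub("\r", "/", names(tab)[tab != J]), 5), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(key_it(site_covariates)))
    stop("duplicated transect-year rows in site_covariates", call. = FALSE)
  miss <- setdiff(site_years, key_it(site_covariates))
  if (length(miss))
    stop("site covariates missing for transect-year(s): ",
         paste(head(gsub("\r", "/", miss), 5), collapse = ", "), call. = FALSE)
  keys_obs <- paste(key_it(obs_covariates), obs_covariates$visit, sep = "\r")
  keys_cnt <- paste(key_it(counts), counts$visit, sep = "\r")
  if (anyDuplicated(keys_obs))
    stop("duplicated transect-year-visit rows in obs_covariates", call. = FALSE)
  miss <- setdiff(keys_cnt, keys_obs)
  if (length(miss))
    stop("observation covariates missing for ", length(miss),
         " transect-year-visit row(s)", call. = FALSE)

  # restrict covariate tables to the surveyed site-years, in counts order
  site_covariates <- site_covariates[match(site_years, key_it(site_covariates)), ,
                                     drop = FALSE]
  obs_covariates <- obs_covariates[match(keys_cnt, keys_obs), , drop = FALSE]
  rownames(counts) <- rownames(site_covariates) <- rownames(obs_covariates) <- NULL

  for (block in list(paste0("veg", 1:4), paste0("water", 1:4),
                     paste0("litter", 1:4))) {
    pm <- as.matrix(site_covariates[block])
    if (any(pm < -1e-9 | pm > 1 + 1e-9))
      stop("category proportions must lie in [0, 1] (", block[1], " block)",
           call. = FALSE)
    s <- rowSums(pm)
    bad <- which(abs(s - 1) > 1e-9)
    if (length(bad))
      stop("category proportions must sum to 1 (", sub("1$", "", block[1]),
           " block); offending row(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }

  structure(list(counts = counts,
                 site_covariates = site_covariates,
                 obs_covariates = obs_covariates,
                 years = sort(unique(counts$year)),
                 J = J),
            class = "survey_dataset")
}

site_cov_columns <- function() {
  c(paste0("veg", 1:4), paste0("water", 1:4), paste0("litter", 1:4))
}

check_columns <- function(d, cols, what) {
  if (!is.data.frame(d)) stop(what, " must be a data frame", call. = FALSE)
  miss <- setdiff(cols, names(d))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d
}

canonical_order <- function(d, keys) {
  d[do.call(order, d[keys]), , drop = FALSE]
}

#' @export
print.survey_dataset <- function(x, ...) {
  n_it <- nrow(x$site_covariates)
  cat("Repeated transect count survey\n")
  cat(sprintf("  %d transects, %d year(s) (%s), %d visits per transect-year\n",
              length(unique(x$counts$transect)), length(x$years),
              paste(range(x$years), collapse = "-"), x$J))
  y <- x$counts$count
  cat(sprintf("  %d transect-years; counts: mean %.1f, sd %.1f, range %d-%d (%d missing)\n",
              n_it, mean(y, na.rm = TRUE), sd(y, na.rm = TRUE),
              min(y, na.rm = TRUE), max(y, na.rm = TRUE), sum(is.na(y))))
  invisible(x)
}

#' Read a survey dataset from its three CSV files
#'
#' Files are UTF-8, comma-separated, with a header row and `.` as the decimal
#' mark (the layout written by [write_survey_dataset()]).  All validation of
#' [survey_dataset()] is applied; malformed input fails with an error naming
#' the offending column or row.
#'
#' @param counts_path,site_cov_path,obs_cov_path paths to `counts.csv`,
#'   `site_covariates.csv` and `obs_covariates.csv`.
#' @return A validated [survey_dataset()].
#' @export
read_survey_dataset <- function(counts_path, site_cov_path, obs_cov_path) {
  survey_dataset(read.csv(counts_path, fileEncoding = "UTF-8"),
                 read.csv(site_cov_path, fileEncoding = "UTF-8"),
                 read.csv(obs_cov_path, fileEncoding = "UTF-8"))
}

#' Write a survey dataset to three CSV files
#'
#' Numeric columns are serialised with 17 significant digits so that a
#' write/read round trip reproduces every double bit-for-bit.
#'
#' @param dataset a [survey_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_survey_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.csv", "site_covariates.csv",
                            "obs_covariates.csv"))
  tabs <- list(dataset$counts, dataset$site_covariates, dataset$obs_covariates)
  for (i in seq_along(tabs)) {
    d <- tabs[[i]]
    for (cn in names(d))
      if (is.double(d[[cn]]))
        d[[cn]] <- sprintf("%.17g", d[[cn]])
    write.csv(d, paths[i], row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  }
  invisible(paths)
}

#' Per-round total counts
#'
#' Sums counts over all transects for each year x visit ("round"), the
#' quantity a traditional uncorrected census reports.  Missing visits are
#' dropped from the sum.
#'
#' @param dataset a [survey_dataset()].
#' @return A matrix with one row per year and one column per visit.
#' @export
round_totals <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  cn <- dataset$counts
  tot <- tapply(cn$count, list(factor(cn$year, levels = dataset$years),
                               factor(cn$visit, levels = seq_len(dataset$J))),
                sum, na.rm = TRUE)
  m <- matrix(as.numeric(tot), nrow = length(dataset$years),
              dimnames = list(year = dataset$years,
                              visit = seq_len(dataset$J)))
  m
}
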