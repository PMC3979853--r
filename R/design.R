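ABUND_COVS <- c("water", "litter", "vegetation")
DET_TERMS <- c("Year", "rain", "temperature", "wind", "date", "vegetation")

cov_block <- function(cov) {
  switch(cov,
         vegetation = paste0("veg", 1:4),
         water = paste0("water", 1:4),
         litter = paste0("litter", 1:4),
         stop("unknown site covariate: ", cov, call. = FALSE))
}

cov_labels <- function(cov) {
  switch(cov,
         vegetation = c("veg.41_80", "veg.81_120", "veg.gt120"),
         water = c("water.wet", "water.lt15", "water.gt15"),
         litter = c("litter.2", "litter.3", "litter.4"))
}

obs_column <- function(term) {
  switch(term, rain = "rain_mm", temperature = "temp_c", wind = "wind",
         date = "day_of_season")
}

#' Specify one candidate binomial mixture model
#'
#' A model is defined by the site covariate placed on abundance and the set
#' of terms placed on detection.  The abundance side always contains an
#' intercept and a linear year trend (the monitoring target) in addition to
#' the named covariate; four-category site covariates enter as three coded
#' proportion columns with the first category as reference.
#'
#' @param abundance one of `"water"`, `"litter"`, `"vegetation"`.
#' @param detection character vector drawn from `"Year"`, `"rain"`,
#'   `"temperature"`, `"wind"`, `"date"`, `"vegetation"`; `"constant"` (or an
#'   empty vector) requests intercept-only detection.
#' @return An object of class `nmix_spec`.
#' @examples
#' nmix_spec("water", c("Year", "rain", "vegetation"))
#' nmix_spec("water", "constant")
#' @export
nmix_spec <- function(abundance, detection = "constant") {
  abundance <- match.arg(abundance, ABUND_COVS)
  detection <- unique(as.character(detection))
  detection <- setdiff(detection, "constant")
  bad <- setdiff(detection, DET_TERMS)
  if (length(bad))
    stop("unknown detection term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  detection <- DET_TERMS[DET_TERMS %in% detection]
  label <- paste0(abundance, " | ",
                  if (length(detection)) paste(detection, collapse = " + ")
                  else "constant")
  structure(list(abundance = abundance, detection = detection, label = label),
            class = "nmix_spec")
}

#' @export
print.nmix_spec <- function(x, ...) {
  cat("N-mixture model spec:", x$label, "\n")
  invisible(x)
}

#' The candidate model set
#'
#' Enumerates the 45 candidate models considered for model selection: each
#' of the three abundance covariates (water depth, litter cover, vegetation
#' height) crossed with 15 detection structures.  The detection structures
#' are built from a base term B in \{constant, rain, temperature, wind,
#' date\} in three tiers: B alone, B + vegetation height, and
#' Year + B + vegetation height (year differences in detectability are only
#' entertained together with the vegetation effect).
#'
#' @return A list of 45 [nmix_spec()] objects.
#' @export
candidate_specs <- function() {
  specs <- list()
  for (a in ABUND_COVS)
    for (b in c("constant", "rain", "temperature", "wind", "date")) {
      base <- if (b == "constant") character(0) else b
      specs <- c(specs, list(
        nmix_spec(a, base),
        nmix_spec(a, c(base, "vegetation")),
        nmix_spec(a, c("Year", base, "vegetation"))))
    }
  specs
}

#' Build design matrices for a model specification
#'
#' Translates a [survey_dataset()] and an [nmix_spec()] into the abundance
#' design matrix `X` (one row per transect-year) and the detection design
#' matrix `W` (one row per transect-year-visit).  The year trend is coded
#' 0, 1, 2, ... from the first year, so the abundance intercept is the
#' first-year baseline on the log scale.  Continuous observation covariates
#' are z-standardised over all visit rows; the constants are returned so
#' fitted coefficients can be mapped back to natural units.
#'
#' @param dataset a [survey_dataset()].
#' @param spec an [nmix_spec()].
#' @param year_coding `"contrast"` codes year differences in detection
#'   relative to the first year (reference-cell coding, used by the
#'   maximum-likelihood stage); `"means"` gives each year its own detection
#'   intercept (used by the Bayesian trend model).
#' @return A list of class `nmix_design` with elements `X`, `W`, `y` (the
#'   count matrix, site-years x visits), `maxy`, `site_index`, `transect`
#'   (factor, one level per transect), `year_of_site`, `std`
#'   (standardisation constants) and `k` (total free-parameter count).
#' @export
build_design <- function(dataset, spec, year_coding = c("contrast", "means")) {
  stopifnot(inherits(dataset, "survey_dataset"), inherits(spec, "nmix_spec"))
  year_coding <- match.arg(year_coding)

  site <- dataset$site_covariates
  n <- nrow(site)
  J <- dataset$J
  years <- dataset$years
  T_ <- length(years)
  trend <- match(site$year, years) - 1

  X <- cbind(1, trend, as.matrix(site[cov_block(spec$abundance)[-1]]))
  colnames(X) <- c("(Intercept)", "trend", cov_labels(spec$abundance))

  obs <- dataset$obs_covariates
  use_year <- "Year" %in% spec$detection || year_coding == "means"
  if (year_coding == "means" && use_year) {
    W <- sapply(years, function(yy) as.numeric(obs$year == yy))
    colnames(W) <- paste0("year", years)
  } else if (use_year) {
    W <- cbind(1, sapply(years[-1], function(yy) as.numeric(obs$year == yy)))
    colnames(W) <- c("(Intercept)", paste0("year", years[-1]))
  } else {
    W <- matrix(1, nrow(obs), 1, dimnames = list(NULL, "(Intercept)"))
  }

  std <- list()
  for (term in intersect(spec$detection, c("rain", "temperature", "wind", "date"))) {
    v <- obs[[obs_column(term)]]
    mu <- mean(v, na.rm = TRUE)
    sdv <- sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    std[[term]] <- c(mean = mu, sd = sdv)
    W <- cbind(W, (v - mu) / sdv)
    colnames(W)[ncol(W)] <- term
  }
  if ("vegetation" %in% spec$detection) {
    vm <- as.matrix(site[cov_block("vegetation")[-1]])
    idx <- match(paste(obs$transect, obs$year), paste(site$transect, site$year))
    W <- cbind(W, vm[idx, , drop = FALSE])
    colnames(W)[(ncol(W) - 2):ncol(W)] <- cov_labels("vegetation")
  }

  y <- matrix(dataset$counts$count, nrow = n, ncol = J, byrow = TRUE)
  maxy <- apply(y, 1, function(r) max(c(r, 0L), na.rm = TRUE))

  structure(list(X = X, W = W, y = y, maxy = as.integer(maxy),
                 site_index = site[c("transect", "year")],
                 transect = factor(site$transect),
                 year_of_site = match(site$year, years),
                 n_years = T_, J = J, std = std, spec = spec,
                 year_coding = year_coding,
                 k = ncol(X) + ncol(W)),
            class = "nmix_design")
}
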