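#' Gaussian feature model of the five rhythm classes
#'
#' Per-class, per-feature normal parameters (mean, sd) for the six
#' centroid features.  `default_table1_model()` returns the published
#' feature distribution of the observed MIT-BIH-derived samples: frequency
#' (Hz) and power of the marginal-spectrum centroid for IMF1--IMF3 of each
#' symptom.
#'
#' @param pars Data frame with columns `symptom` (1--5), `feature` (one of
#'   `f1_freq,f1_pow,f2_freq,f2_pow,f3_freq,f3_pow`), `mu`, `sd`.
#' @return Object of class `"gaussian_feature_model"`.
#' @export
gaussian_feature_model <- function(pars) {
  pars <- as.data.frame(pars)
  stopifnot(all(c("symptom", "feature", "mu", "sd") %in% names(pars)))
  full <- expand.grid(feature = feature_cols, symptom = 1:5,
                      stringsAsFactors = FALSE)
  key <- paste(pars$symptom, pars$feature)
  miss <- !(paste(full$symptom, full$feature) %in% key)
  if (any(miss))
    stop("missing (mu, sd) entries: ",
         paste(paste0(symptom_names[full$symptom[miss]], "/",
                      full$feature[miss]), collapse = ", "))
  if (any(pars$sd < 0)) stop("sd must be >= 0")
  rownames(pars) <- NULL
  structure(pars[c("symptom", "feature", "mu", "sd")],
            class = c("gaussian_feature_model", "data.frame"))
}

#' @rdname gaussian_feature_model
#' @export
default_table1_model <- function() {
  # (mu, sd) per feature, in class order NSR, APC, AFib, VPC, VT
  cells <- list(
    f1_freq = c(4.772, 0.787,  4.241, 0.798,  3.571, 0.558,
                3.283, 0.973,  3.120, 1.123),
    f1_pow  = c(1.167, 0.864,  0.791, 0.567,  2.683, 1.214,
                3.196, 2.170,  6.504, 6.250),
    f2_freq = c(1.478, 0.527,  0.932, 0.504,  1.049, 0.455,
                0.993, 0.503,  1.013, 0.489),
    f2_pow  = c(1.344, 1.605,  1.223, 1.294,  2.824, 2.053,
                4.548, 3.909,  6.923, 7.274),
    f3_freq = c(0.288, 0.261,  0.378, 0.257,  0.327, 0.263,
                0.340, 0.264,  0.315, 0.265),
    f3_pow  = c(0.645, 1.997,  1.461, 2.762,  1.183, 2.024,
                1.449, 2.011,  1.184, 1.070))
  pars <- do.call(rbind, lapply(names(cells), function(f) {
    v <- cells[[f]]
    data.frame(symptom = 1:5, feature = f,
               mu = v[seq(1, 9, 2)], sd = v[seq(2, 10, 2)])
  }))
  gaussian_feature_model(pars)
}

#' Look up one (mu, sd) pair of a Gaussian feature model
#' @param model A [gaussian_feature_model()].
#' @param symptom Symptom ID 1--5.
#' @param feature Feature name, e.g. `"f1_pow"`.
#' @return Named numeric `c(mu, sd)`.
#' @export
model_lookup <- function(model, symptom, feature) {
  row <- model[model$symptom == symptom & model$feature == feature, ]
  if (nrow(row) != 1L) stop("no entry for symptom ", symptom, ", ", feature)
  c(mu = row$mu, sd = row$sd)
}

#' Simulate a balanced feature-space data set from a Gaussian model
#'
#' Draws `n_per_symptom` records for each of the five symptoms; every
#' feature is drawn independently from its class-conditional normal
#' distribution (the simulative-data construction of the study, where a
#' balanced set of 1000 records per symptom stands in for the scarce
#' observed classes).  Negative frequency or power draws are truncated at
#' 0 by default, since both are physically non-negative; the truncated
#' fraction is attached as attribute `"truncation_rate"`.
#'
#' @param model A [gaussian_feature_model()].
#' @param n_per_symptom Records per class (>= 1).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param truncate_at_zero Clamp negative draws to 0 (default `TRUE`).
#' @return A [feature_table()] with `5 * n_per_symptom` rows, classes in
#'   blocks 1..5.
#' @export
simulate_features <- function(model, n_per_symptom, seed = 1,
                              truncate_at_zero = TRUE) {
  if (n_per_symptom < 1) stop("n_per_symptom must be >= 1")
  if (!inherits(model, "gaussian_feature_model"))
    model <- gaussian_feature_model(model)
  set.seed(as.integer(seed))
  n_trunc <- 0L
  blocks <- lapply(1:5, function(s) {
    cols <- lapply(feature_cols, function(f) {
      ms <- model_lookup(model, s, f)
      v <- stats::rnorm(n_per_symptom, ms["mu"], ms["sd"])
      if (truncate_at_zero) {
        n_trunc <<- n_trunc + sum(v < 0)
        v <- pmax(v, 0)
      }
      v
    })
    names(cols) <- feature_cols
    feature_table(as.data.frame(cols), s)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "truncation_rate") <- n_trunc / (5 * n_per_symptom * 6)
  out
}
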