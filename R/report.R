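# Cohort-level comparison and end-to-end pipeline: paired condition
# contrasts on spine parameters, Pearson validation of model predictions
# against measurements, and a reproducible report bundle.

#' Paired contrasts of spine parameters across conditions
#'
#' For every parameter and every pair of conditions, computes the
#' participant-wise paired differences (first minus second condition, in
#' the order the conditions appear), their mean and SD, a paired two-sided
#' t statistic and p-value, and a Holm-adjusted p-value over the condition
#' pairs within each parameter.  The crossover design requires every
#' participant to have every condition.
#'
#' Degenerate zero-variance differences (e.g. an SD-0 synthetic cohort)
#' have no t distribution; the convention used is p = 1 when the
#' differences are identically zero and p = 0 (statistic +/-Inf) when they
#' are constant but non-zero.
#'
#' @param params data frame with columns `participant`, `condition` and one
#'   column per spine parameter (`TI_deg`, `HD_mm`, `CLD_mm`, `LLD_mm`).
#' @return data frame of class `spine_contrasts`: one row per
#'   parameter x condition pair with `mean_diff`, `sd_diff`, `statistic`,
#'   `p_value`, `p_adj`.
#' @export
paired_contrasts <- function(params) {
  pn <- intersect(c("TI_deg", "HD_mm", "CLD_mm", "LLD_mm"), names(params))
  if (!length(pn)) stop("no spine-parameter columns found")
  conds <- if (is.factor(params$condition)) levels(params$condition) else
    unique(params$condition)
  ids <- sort(unique(params$participant))
  for (id in ids) {
    have <- params$condition[params$participant == id]
    miss <- setdiff(conds, as.character(have))
    if (length(miss)) {
      stop("participant ", id, " is missing condition(s): ",
           paste(miss, collapse = ", "))
    }
  }
  if (length(conds) < 2) {
    out <- data.frame(parameter = character(0), pair = character(0),
                      mean_diff = numeric(0), sd_diff = numeric(0),
                      statistic = numeric(0), p_value = numeric(0),
                      p_adj = numeric(0))
    class(out) <- c("spine_contrasts", "data.frame")
    return(out)
  }
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  rows <- list()
  for (par in pn) {
    pvals <- numeric(length(pairs))
    prow <- vector("list", length(pairs))
    for (k in seq_along(pairs)) {
      a <- pairs[[k]][1]; b <- pairs[[k]][2]
      va <- params[[par]][match(paste(ids, a),
                                paste(params$participant, params$condition))]
      vb <- params[[par]][match(paste(ids, b),
                                paste(params$participant, params$condition))]
      d <- va - vb
      m <- mean(d); s <- stats::sd(d)
      if (s < 1e-12) {
        stat <- if (abs(m) < 1e-12) 0 else sign(m) * Inf
        p <- if (abs(m) < 1e-12) 1 else 0
      } else {
        tt <- stats::t.test(d)
        stat <- unname(tt$statistic)
        p <- tt$p.value
      }
      pvals[k] <- p
      prow[[k]] <- data.frame(parameter = par,
                              pair = paste0(a, "-", b),
                              mean_diff = m, sd_diff = s,
                              statistic = stat, p_value = p)
    }
    adj <- stats::p.adjust(pvals, method = "holm")
    for (k in seq_along(prow)) prow[[k]]$p_adj <- adj[k]
    rows <- c(rows, prow)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("spine_contrasts", "data.frame")
  out
}

#' Pearson validation of predicted against reference values
#'
#' Standard Pearson correlation, labelled "strong" when r lies in
#' [0.7, 1.0] (the conventional threshold for a strong positive linear
#' relationship).
#'
#' @param predicted,reference numeric vectors of equal length (>= 3), each
#'   with non-zero variance.
#' @return list with `r`, `p_value` and `strength` ("strong" or
#'   "not strong").
#' @export
validate_correlation <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  if (length(predicted) < 3) stop("need at least 3 paired values")
  if (stats::sd(predicted) == 0 || stats::sd(reference) == 0) {
    stop("undefined correlation: zero variance")
  }
  ct <- stats::cor.test(predicted, reference)
  r <- unname(ct$estimate)
  list(r = r, p_value = ct$p.value,
       strength = if (r >= 0.7 && r <= 1.0) "strong" else "not strong")
}

#' Synthetic validation sweep: model predictions vs generator ground truth
#'
#' Draws spine-parameter sets per mattress condition, builds a body whose
#' rest back profile is the corresponding synthetic curve, solves the
#' supine equilibrium on that condition's mattress (with the cervical
#' pillow fitted at the shoulder line), extracts the spine parameters of
#' the deformed curve, and pools all parameters across scenarios into one
#' predicted-vs-truth Pearson correlation -- the validation logic of a
#' jitter-plot comparison between computation and experiment.
#'
#' @param n_per_condition scenarios per condition.
#' @param seed integer seed.
#' @param conditions per-condition parameter distributions
#'   ([default_conditions()]).
#' @param library material library ([foam_library()]).
#' @param height_cm,mass_kg subject anthropometry for the body model.
#' @return list with `table` (scenario, condition, parameter, truth,
#'   predicted), `r`, and `strength`.
#' @export
validation_sweep <- function(n_per_condition = 10, seed = 1,
                             conditions = default_conditions(),
                             library = foam_library(),
                             height_cm = 176, mass_kg = 74) {
  spec <- cohort_spec(n_participants = n_per_condition,
                      conditions = conditions, seed = seed, noise_mm = 0)
  draws <- generate_cohort(spec, curves = FALSE)$params
  rows <- list()
  for (i in seq_len(nrow(draws))) {
    pr <- draws[i, ]
    prof <- make_profile(pr$TI_deg, pr$HD_mm, pr$CLD_mm, pr$LLD_mm)
    body <- build_default_body(height_cm, mass_kg, rest_curve = prof)
    surf <- support_surface(as.character(pr$condition), "pillow",
                            pillow_extent_mm = fit_pillow_extent(body),
                            library = library)
    res <- solve_equilibrium(body, surf)
    pred <- suppressWarnings(extract_spine_params(res$curve))
    for (par in c("TI_deg", "HD_mm", "CLD_mm", "LLD_mm")) {
      key <- sub("_(deg|mm)$", "", par)
      rows[[length(rows) + 1]] <- data.frame(
        scenario = i, condition = as.character(pr$condition),
        parameter = par, truth = pr[[par]],
        predicted = switch(key, TI = pred$TI_deg, HD = pred$HD_mm,
                           CLD = pred$CLD_mm, LLD = pred$LLD_mm))
    }
  }
  tab <- do.call(rbind, rows)
  v <- validate_correlation(tab$predicted, tab$truth)
  list(table = tab, r = v$r, strength = v$strength)
}

#' Run the full analysis pipeline
#'
#' Generates a synthetic crossover cohort, simulates the tape measurement
#' of every back profile and re-extracts the spine parameters from the
#' reconstructed curves, computes paired per-mattress contrasts on the
#' cohort parameter table, solves the supine equilibrium for the default
#' subject on every mattress, and validates the model-predicted spine
#' parameters against the measured (tape-extracted) condition means by
#' Pearson correlation.  Fully reproducible from the config and seed.
#'
#' @param config optional list (or YAML file path) with any of
#'   `n_participants`, `noise_mm`, `rho`, `conditions`, `registry`,
#'   `height_cm`, `mass_kg`; missing entries take the package defaults.
#' @param seed integer seed for all randomness.
#' @param out_dir optional output directory; when given, writes
#'   `manifest.csv`, `measured_params.csv`, `contrasts.csv`,
#'   `mechanics.json` and `report.json`.
#' @return object of class `spinemat_report`.
#' @export
run_pipeline <- function(config = NULL, seed = 1, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  get <- function(nm, default) if (!is.null(config[[nm]])) config[[nm]] else default
  conditions <- get("conditions", default_conditions())
  spec <- cohort_spec(n_participants = get("n_participants", 16),
                      conditions = conditions,
                      seed = seed,
                      noise_mm = get("noise_mm", 0.5),
                      rho = get("rho", 0.5))
  lib <- if (!is.null(config$registry)) foam_library(config$registry) else
    foam_library()

  cohort <- generate_cohort(spec, curves = TRUE)

  # tape reconstruction and parameter re-extraction per cell
  meas <- list()
  for (i in seq_len(nrow(cohort$params))) {
    p <- cohort$params[i, ]
    cell <- cohort$curves[[p$participant]][[as.character(p$condition)]]
    crv <- suppressWarnings(chain_elements(cell$elements))
    sp <- suppressWarnings(extract_spine_params(crv))
    meas[[i]] <- cbind(p[, c("participant", "condition")],
                       as.data.frame(sp))
  }
  measured <- do.call(rbind, meas)

  contrasts <- paired_contrasts(cohort$params)

  # mechanics per condition for the default subject
  body <- build_default_body(get("height_cm", 176), get("mass_kg", 74))
  pe <- fit_pillow_extent(body)
  mech <- list()
  for (cond in names(conditions)) {
    res <- solve_equilibrium(body, support_surface(cond, "pillow",
                                                   pillow_extent_mm = pe,
                                                   library = lib))
    sp <- suppressWarnings(extract_spine_params(res$curve))
    cp <- contact_pressure_profile(res)
    ca <- contact_area(res)
    mech[[cond]] <- list(
      spine_params = as.data.frame(sp),
      region_peaks_kPa = as.list(cp$region_peaks_kPa),
      contact_area_cm2 = ca,
      disc_region_peaks_kPa =
        as.list(attr(res$disc_stress, "region_peaks_kPa")),
      balance_rel = res$balance_rel)
  }

  # validation: model-predicted vs measured condition means, pooled over
  # parameters
  pn <- c("TI_deg", "HD_mm", "CLD_mm", "LLD_mm")
  pred <- unlist(lapply(names(conditions),
                        function(cond) unlist(mech[[cond]]$spine_params[pn])))
  ref <- unlist(lapply(names(conditions), function(cond) {
    colMeans(measured[measured$condition == cond, pn])
  }))
  validation <- validate_correlation(as.numeric(pred), as.numeric(ref))

  report <- structure(list(cohort = cohort, measured = measured,
                           contrasts = contrasts, mechanics = mech,
                           validation = validation, seed = seed),
                      class = "spinemat_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.spinemat_report <- function(x, ...) {
  cat("<spinemat_report> seed ", x$seed, ", ",
      x$cohort$spec$n_participants, " participants x ",
      length(x$cohort$spec$conditions), " conditions\n", sep = "")
  cat("Key paired contrasts (parameter pair: mean diff +/- SD):\n")
  ct <- x$contrasts
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("  %-6s %-6s %7.2f +/- %5.2f  (p_adj %.3g)\n",
                ct$parameter[i], ct$pair[i], ct$mean_diff[i], ct$sd_diff[i],
                ct$p_adj[i]))
  }
  cat(sprintf("Validation: Pearson r = %.3f (%s)\n",
              x$validation$r, x$validation$strength))
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' @param report a `spinemat_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cbind(report$cohort$params, seed = report$seed),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  long <- stats::reshape(
    report$measured, direction = "long",
    varying = c("TI_deg", "HD_mm", "CLD_mm", "LLD_mm"),
    v.names = "value", timevar = "parameter",
    times = c("TI_deg", "HD_mm", "CLD_mm", "LLD_mm"))
  long <- long[order(long$participant, long$condition, long$parameter),
               c("participant", "condition", "parameter", "value")]
  utils::write.csv(long, file.path(out_dir, "measured_params.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$contrasts),
                   file.path(out_dir, "contrasts.csv"), row.names = FALSE)
  jsonlite::write_json(report$mechanics,
                       file.path(out_dir, "mechanics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = report$seed,
                            validation = report$validation),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
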