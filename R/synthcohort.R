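#' Default synthetic chronic-fatigue scenario
#'
#' A two-cohort plasma-metabolome scenario over the 31 metabolites of the
#' bundled pathway map plus common plasma amino acids. Baselines are typical
#' plasma concentrations (micromolar, lognormal medians); case effects are
#' multiplicative fold-changes with the directions reported for chronic
#' fatigue: TCA intermediates (citrate, cis-aconitate, isocitrate, malate),
#' urea and citrulline down; ornithine up; pyruvate slightly up; glucose,
#' glutamine/glutamate, succinate and the branched-chain amino acids
#' unchanged. Cohort sizes are 47 cases / 46 controls (training) and 20/20
#' (validation). Noise: biological log-SD 0.35, per-sample diurnal log-SD
#' 0.30 shared by all metabolites of a sample, analytical log-SD 0.05.
#' Detection limits left-censor low concentrations to missing and drive the
#' S/N model `sn = concentration / detection_limit * base_sn` (base 5).
#'
#' @return A `synth_scenario` list: `metabolites` (id, mode, baseline_um,
#'   fold_change, detection_limit_um), `biological_cv`, `diurnal_sigma`,
#'   `analytical_cv`, `base_sn`, `cohort_sizes`, `is_area_meanlog`,
#'   `is_area_sdlog`.
#' @export
default_cfs_scenario <- function() {
  m <- function(id, mode, base, dl, fc = 1)
    data.frame(metabolite_id = id, mode = mode, baseline_um = base,
               detection_limit_um = dl, fold_change = fc,
               stringsAsFactors = FALSE)
  mets <- rbind(
    m("glucose",              "anion",  5000, 50),
    m("glucose-6-phosphate",  "anion",    30, 1),
    m("fructose-6-phosphate", "anion",    10, 0.5),
    m("3-phosphoglycerate",   "anion",    15, 0.5),
    m("phosphoenolpyruvate",  "anion",     8, 0.5),
    m("pyruvate",             "anion",    60, 2,    1.12),
    m("lactate",              "anion",  1500, 20),
    m("citrate",              "anion",   120, 4,    0.85),
    m("cis-aconitate",        "anion",   2.5, 0.2,  0.90),
    m("isocitrate",           "anion",     5, 1,    0.75),
    m("2-oxoglutarate",       "anion",    10, 0.5),
    m("succinate",            "anion",     5, 0.3),
    m("fumarate",             "anion",     2, 0.15),
    m("malate",               "anion",    10, 0.5,  0.85),
    m("urea",                 "cation", 4000, 100,  0.80),
    m("ornithine",            "cation",   60, 2,    1.30),
    m("citrulline",           "cation",   30, 1,    0.78),
    m("argininosuccinate",    "cation",  1.2, 0.9),
    m("arginine",             "cation",   90, 3),
    m("glutamine",            "cation",  550, 10),
    m("glutamate",            "cation",   50, 2),
    m("GABA",                 "cation", 0.25, 0.18),
    m("alanine",              "cation",  350, 10),
    m("valine",               "cation",  220, 5),
    m("leucine",              "cation",  120, 5),
    m("isoleucine",           "cation",   60, 2),
    m("aspartate",            "cation",    8, 0.4),
    m("asparagine",           "cation",   45, 2),
    m("methionine",           "cation",   25, 1),
    m("tyrosine",             "cation",   60, 2),
    m("creatinine",           "cation",   70, 2))
  structure(list(
    metabolites = mets,
    biological_cv = 0.35,
    diurnal_sigma = 0.30,
    analytical_cv = 0.05,
    base_sn = 5,
    cohort_sizes = list(training = c(case = 47L, control = 46L),
                        validation = c(case = 20L, control = 20L)),
    is_area_meanlog = log(1e5),
    is_area_sdlog = 0.2), class = "synth_scenario")
}

#' Serialize / load a synthetic scenario
#'
#' @param scenario A `synth_scenario`.
#' @param path YAML file path.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "synth_scenario"))
  s <- unclass(scenario)
  s$metabolites <- as.list(s$metabolites)
  s$cohort_sizes <- lapply(s$cohort_sizes, as.list)
  yaml::write_yaml(s, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  s <- yaml::read_yaml(path)
  s$metabolites <- as.data.frame(s$metabolites, stringsAsFactors = FALSE)
  s$cohort_sizes <- lapply(s$cohort_sizes, unlist)
  structure(s, class = "synth_scenario")
}

#' Generate one synthetic cohort of peak-table data
#'
#' Latent concentration of sample j, metabolite i:
#' `baseline_i * fold_change_i^[case_j] * exp(bio_cv * Z_ij) * s_j`, with
#' `s_j = exp(diurnal_sigma * Z_j)` a global per-sample scale shared by all
#' metabolites (diurnal variation). The measured value multiplies in
#' lognormal analytical noise. Latent values below the detection limit are
#' left-censored: no peak record is emitted. Peak areas are back-computed
#' through the calibration standards and per-run internal-standard areas, so
#' [quantify()] inverts the generator up to analytical noise. S/N per record
#' is `measured / detection_limit * base_sn`.
#'
#' All random draws happen in a fixed order with sizes independent of the
#' noise magnitudes, so two runs with the same seed differing only in
#' `diurnal_sigma` share every other noise realisation.
#'
#' @param scenario A `synth_scenario`.
#' @param cohort `"training"` or `"validation"`.
#' @param seed Integer seed.
#' @return `list(peaks, samples, standards, latent)`; `latent` is the
#'   uncensored samples-by-metabolites latent concentration matrix.
#' @export
generate_cohort <- function(scenario, cohort = c("training", "validation"),
                            seed = 1L) {
  stopifnot(inherits(scenario, "synth_scenario"))
  cohort <- match.arg(cohort)
  sizes <- scenario$cohort_sizes[[cohort]]
  n_case <- sizes[["case"]]; n_ctrl <- sizes[["control"]]
  n <- n_case + n_ctrl
  mets <- scenario$metabolites
  k <- nrow(mets)
  prefix <- toupper(substr(cohort, 1, 2))
  samples <- data.frame(
    sample_id = c(sprintf("%s_CASE_%02d", prefix, seq_len(n_case)),
                  sprintf("%s_CTRL_%02d", prefix, seq_len(n_ctrl))),
    cohort = cohort,
    group = rep(c("case", "control"), c(n_case, n_ctrl)),
    stringsAsFactors = FALSE)

  set.seed(seed)
  z_bio <- matrix(rnorm(n * k), n, k)
  z_ana <- matrix(rnorm(n * k), n, k)
  z_diu <- rnorm(n)
  is_area <- matrix(exp(rnorm(2 * n, scenario$is_area_meanlog,
                              scenario$is_area_sdlog)),
                    n, 2, dimnames = list(samples$sample_id, MODE_LEVELS))

  fc <- ifelse(samples$group == "case", 1, 0)
  latent <- t(vapply(seq_len(n), function(j) {
    mets$baseline_um * mets$fold_change^fc[j] *
      exp(scenario$biological_cv * z_bio[j, ]) *
      exp(scenario$diurnal_sigma * z_diu[j])
  }, numeric(k)))
  dimnames(latent) <- list(samples$sample_id, mets$metabolite_id)
  measured <- latent * exp(scenario$analytical_cv * z_ana)

  standards <- data.frame(
    metabolite_id = mets$metabolite_id,
    mode = mets$mode,
    standard_concentration = mets$baseline_um,
    standard_relative_area = 0.5 + (seq_len(k) %% 7) / 10,
    stringsAsFactors = FALSE)

  detected <- latent >= matrix(mets$detection_limit_um, n, k, byrow = TRUE)
  idx <- which(detected, arr.ind = TRUE)
  j <- idx[, 1]; i <- idx[, 2]
  conc <- measured[detected]
  rel <- conc / standards$standard_concentration[i] *
    standards$standard_relative_area[i]
  isa <- is_area[cbind(j, match(mets$mode[i], MODE_LEVELS))]
  peaks <- data.frame(
    sample_id = samples$sample_id[j],
    metabolite_id = mets$metabolite_id[i],
    mode = mets$mode[i],
    peak_area = rel * isa,
    sn_ratio = conc / mets$detection_limit_um[i] * scenario$base_sn,
    is_area = isa,
    stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$sample_id, peaks$metabolite_id), ]
  rownames(peaks) <- NULL
  list(peaks = peaks, samples = samples, standards = standards,
       latent = latent)
}

#' Hand-written worked example fixture
#'
#' Six samples by six metabolites with known answers: `m1` separates the
#' three cases {4, 5, 6} from the three controls {1, 2, 3} (exact two-sided
#' Mann-Whitney p = 0.100), `m2` is identical across groups (p = 1), `m3`
#' has one missing cell whose half-minimum imputation is 2.0, `m5` is
#' constant. A designated 2-case/2-control score vector has AUC 0.75
#' (3 of 4 concordant pairs).
#'
#' @return `list(matrix, samples, scores, score_labels)`.
#' @export
generate_worked_example <- function() {
  vals <- matrix(c(
    #  m1   m2   m3    m4   m5   m6
       4,   7,   4,    9,   1,  0.5,
       5,   8,   8,    8,   1,  2.0,
       6,   9,  12,    7,   1,  1.5,
       1,   7,  NA,   12,   1,  0.8,
       2,   8,   6,   11,   1,  1.2,
       3,   9,  10,   10,   1,  0.9),
    nrow = 6, byrow = TRUE,
    dimnames = list(c("WX_CASE_01", "WX_CASE_02", "WX_CASE_03",
                      "WX_CTRL_01", "WX_CTRL_02", "WX_CTRL_03"),
                    paste0("m", 1:6)))
  samples <- data.frame(
    sample_id = rownames(vals),
    cohort = "training",
    group = rep(c("case", "control"), each = 3),
    stringsAsFactors = FALSE)
  list(matrix = metabolite_matrix(vals, provenance = "quantified"),
       samples = samples,
       scores = c(WX_CASE_01 = 0.4, WX_CASE_02 = 0.8,
                  WX_CTRL_01 = 0.2, WX_CTRL_02 = 0.6),
       score_labels = c("case", "case", "control", "control"))
}
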