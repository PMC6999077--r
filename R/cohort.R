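#' Configure a synthetic thickness-versus-age cohort
#'
#' One row per eye with the nine thickness metrics (total/inner/outer x
#' whole/superior/inferior annulus) generated from a linear age model:
#' `thickness = baseline - slope * age + N(0, sigma)`. The inner and outer
#' compartments are generated separately in each half (superior/inferior)
#' with compartment-scaled baselines, slopes and noise; the whole-annulus
#' value is the mean of the two halves and the total is the sum of inner
#' and outer, so total = inner + outer holds by construction.
#'
#' Defaults emulate the study conditions of the reference cohort: 44
#' transgenic and 28 wild-type eyes aged 45 to 104 weeks, total thinning
#' slopes 0.37 and 0.26 um/week, and a residual scatter of 5 um.
#'
#' @param groups named list (one entry per group) of lists with fields
#'   `n_eyes`, `age_range_weeks`, `baseline_um` (total thickness at age 0),
#'   `slope_um_per_week` (total thinning rate, positive = thinning),
#'   `sigma_um` (residual SD of the total thickness).
#' @param inner_fraction fraction of baseline thickness in the inner
#'   retina.
#' @param inner_slope_fraction fraction of the thinning slope attributed to
#'   the inner retina.
#' @param seed RNG seed.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(groups = list(
                            transgenic = list(n_eyes = 44L,
                                              age_range_weeks = c(45, 104),
                                              baseline_um = 240,
                                              slope_um_per_week = 0.37,
                                              sigma_um = 5),
                            wildtype = list(n_eyes = 28L,
                                            age_range_weeks = c(45, 104),
                                            baseline_um = 240,
                                            slope_um_per_week = 0.26,
                                            sigma_um = 5)),
                          inner_fraction = 130 / 220,
                          inner_slope_fraction = 0.35,
                          seed = 1L) {
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (!is_count(gr$n_eyes) || gr$n_eyes < 2L)
      stop_retoct(sprintf("group '%s' needs at least 2 eyes", g),
                  "retoct_validation_error")
    if (gr$sigma_um < 0)
      stop_retoct("residual sigma must be non-negative",
                  "retoct_validation_error")
    if (length(gr$age_range_weeks) != 2L ||
        gr$age_range_weeks[2L] < gr$age_range_weeks[1L])
      stop_retoct("age_range_weeks must be an increasing pair",
                  "retoct_validation_error")
  }
  structure(list(groups = groups, inner_fraction = inner_fraction,
                 inner_slope_fraction = inner_slope_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort thickness table
#'
#' @param config a [cohort_config()].
#' @return a data.frame with one row per eye: `eye_id`, `group`,
#'   `age_weeks`, and the nine metric columns `total_whole`, ...,
#'   `outer_inferior` (um).
#' @export
generate_cohort <- function(config = cohort_config()) {
  force(config)   # before the RNG state snapshot: the argument may draw
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  fi <- config$inner_fraction
  fsi <- config$inner_slope_fraction
  rows <- list()
  for (g in names(config$groups)) {
    gr <- config$groups[[g]]
    n <- gr$n_eyes
    age <- stats::runif(n, gr$age_range_weeks[1L], gr$age_range_weeks[2L])
    comp <- list(inner = c(fi * gr$baseline_um, fsi * gr$slope_um_per_week,
                           fi * gr$sigma_um),
                 outer = c((1 - fi) * gr$baseline_um,
                           (1 - fsi) * gr$slope_um_per_week,
                           (1 - fi) * gr$sigma_um))
    vals <- list()
    for (cn in names(comp)) {
      pr <- comp[[cn]]
      for (half in c("superior", "inferior")) {
        mu <- pr[1L] - pr[2L] * age
        vals[[paste0(cn, "_", half)]] <- mu + stats::rnorm(n, 0, pr[3L])
      }
      vals[[paste0(cn, "_whole")]] <-
        (vals[[paste0(cn, "_superior")]] + vals[[paste0(cn, "_inferior")]]) / 2
    }
    df <- data.frame(eye_id = sprintf("%s-%03d", g, seq_len(n)),
                     group = g, age_weeks = age,
                     stringsAsFactors = FALSE)
    for (rg in c("whole", "superior", "inferior")) {
      df[[paste0("total_", rg)]] <- vals[[paste0("inner_", rg)]] +
        vals[[paste0("outer_", rg)]]
      df[[paste0("inner_", rg)]] <- vals[[paste0("inner_", rg)]]
      df[[paste0("outer_", rg)]] <- vals[[paste0("outer_", rg)]]
    }
    rows[[g]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Thickness metric names
#' @return character vector of the nine metric column names.
#' @export
thickness_metrics <- function() {
  as.vector(outer(c("total", "inner", "outer"),
                  c("whole", "superior", "inferior"), paste, sep = "_"))
}
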