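#' Configuration of the single-cell matrix simulator
#'
#' Describes a synthetic single-cell protein matrix with planted
#' structure: two co-expression modules loading with opposite sign on a
#' shared latent cell-state score (strong internal correlation, mutual
#' anti-correlation), an optional set of treatment-responsive proteins
#' shifted by a fixed log2 effect in treated cells, log-normal
#' measurement noise, and logistic intensity-dependent detection
#' (set `detection_midpoint = -Inf` for a fully observed matrix).
#'
#' @param n_proteins Total number of proteins (default 500).
#' @param n_cells_control,n_cells_treated Cells per group (defaults 60).
#' @param module_sizes Integer vector of length 2: sizes of the two
#'   planted modules (default `c(30, 30)`; use `c(0, 0)` for no modules).
#' @param module_strength Log2 loading magnitude on the latent score
#'   (default 1).
#' @param n_responders Number of treatment-responsive proteins (default 50;
#'   responders are drawn outside the modules when possible).
#' @param effect_log2 Log2 shift of responders in treated cells
#'   (default 1).
#' @param baseline_mean,baseline_sd Per-protein baseline log2 abundance
#'   model (defaults 12 and 1.5).
#' @param noise_sd_log2 Log2 measurement noise sd (default 0.5).
#' @param detection_midpoint,detection_slope Logistic detection model on
#'   log2 intensity (defaults 10.5 and 1, giving single-cell-like
#'   missingness concentrated in low-abundance proteins).
#' @param seed Mandatory integer seed.
#' @return A list of class `sc_config`.
#' @export
sc_config <- function(n_proteins = 500L, n_cells_control = 60L,
                      n_cells_treated = 60L, module_sizes = c(30L, 30L),
                      module_strength = 1, n_responders = 50L,
                      effect_log2 = 1, baseline_mean = 12,
                      baseline_sd = 1.5, noise_sd_log2 = 0.5,
                      detection_midpoint = 10.5, detection_slope = 1,
                      seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for the simulator", call. = FALSE)
  }
  if (length(module_sizes) != 2) {
    stop("module_sizes must have length 2", call. = FALSE)
  }
  if (sum(module_sizes) > n_proteins) {
    stop("module sizes exceed the protein count", call. = FALSE)
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_cells_control = as.integer(n_cells_control),
         n_cells_treated = as.integer(n_cells_treated),
         module_sizes = as.integer(module_sizes),
         module_strength = module_strength,
         n_responders = as.integer(n_responders),
         effect_log2 = effect_log2,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         noise_sd_log2 = noise_sd_log2,
         detection_midpoint = detection_midpoint,
         detection_slope = detection_slope,
         seed = as.integer(seed)),
    class = "sc_config"
  )
}

#' Simulate a single-cell protein matrix with planted structure
#'
#' Generates a proteins x cells log2 matrix according to an
#' [sc_config()], with `NA` for undetected cells, and returns the truth:
#' module membership, the responder set, the latent cell-state scores and
#' the group label per cell.
#'
#' @param cfg An [sc_config()].
#' @return A list with `matrix` and `truth` (list with `modules`,
#'   `responders`, `latent`, `groups`).
#' @export
simulate_single_cells <- function(cfg) {
  stopifnot(inherits(cfg, "sc_config"))
  with_preserved_rng(cfg$seed, {
    n_cells <- cfg$n_cells_control + cfg$n_cells_treated
    proteins <- sprintf("PROT_%04d", seq_len(cfg$n_proteins))
    cells <- c(sprintf("ctrl_%03d", seq_len(cfg$n_cells_control)),
               sprintf("treat_%03d", seq_len(cfg$n_cells_treated)))
    groups <- rep(c("control", "treated"),
                  c(cfg$n_cells_control, cfg$n_cells_treated))

    modules <- rep(0L, cfg$n_proteins)
    if (cfg$module_sizes[1] > 0) {
      modules[seq_len(cfg$module_sizes[1])] <- 1L
    }
    if (cfg$module_sizes[2] > 0) {
      modules[cfg$module_sizes[1] + seq_len(cfg$module_sizes[2])] <- 2L
    }
    loading <- ifelse(modules == 1L, cfg$module_strength,
                      ifelse(modules == 2L, -cfg$module_strength, 0))
    free <- which(modules == 0L)
    responders <- if (cfg$n_responders > 0) {
      if (length(free) >= cfg$n_responders) {
        free[seq_len(cfg$n_responders)]
      } else {
        seq_len(min(cfg$n_responders, cfg$n_proteins))
      }
    } else {
      integer(0)
    }

    latent <- rnorm(n_cells)
    baseline <- rnorm(cfg$n_proteins, cfg$baseline_mean, cfg$baseline_sd)
    values <- outer(baseline, rep(1, n_cells)) +
      outer(loading, latent) +
      cfg$effect_log2 * outer(seq_len(cfg$n_proteins) %in% responders,
                              groups == "treated") +
      matrix(rnorm(cfg$n_proteins * n_cells, 0, cfg$noise_sd_log2),
             nrow = cfg$n_proteins)
    p_det <- plogis((values - cfg$detection_midpoint) / cfg$detection_slope)
    detected <- matrix(runif(length(values)), nrow = nrow(values)) < p_det
    values[!detected] <- NA_real_
    dimnames(values) <- list(proteins, cells)
    list(
      matrix = values,
      truth = list(
        modules = setNames(modules, proteins),
        responders = proteins[responders],
        latent = setNames(latent, cells),
        groups = setNames(groups, cells)
      )
    )
  })
}
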