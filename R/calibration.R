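#' Experimental reference table
#'
#' End-to-end distances and radii of gyration used to score the calibration
#' sweep, keyed by degree of polymerization.  Only the dp12 end-to-end
#' distance of 60 Angstrom is shipped as a packaged value; the remaining
#' slots (dp 6, 12, 18, 24, 30, 32, 36, 48, 68) are `NA` placeholders to be
#' filled from the user's own experimental sources via [set_reference()] -
#' no invented numbers.
#'
#' @return A data.frame with columns `dp`, `eed` (Angstrom), `rg` (Angstrom)
#'   and `source`.
#' @export
#' @examples
#' reference_table()
reference_table <- function() {
  df <- data.frame(
    dp = c(6L, 12L, 18L, 24L, 30L, 32L, 36L, 48L, 68L),
    eed = NA_real_, rg = NA_real_, source = NA_character_,
    stringsAsFactors = FALSE
  )
  df$eed[df$dp == 12L] <- 60
  df$source[df$dp == 12L] <- "analytical centrifugation / synchrotron X-ray scattering"
  df
}

#' Fill or override a reference entry
#'
#' @param table A reference table as returned by [reference_table()].
#' @param dp Degree of polymerization (added if absent).
#' @param eed,rg Reference values, Angstrom (`NA` to leave unchanged).
#' @param source Free-text provenance tag.
#' @return The updated table.
#' @export
set_reference <- function(table, dp, eed = NA_real_, rg = NA_real_,
                          source = "user") {
  i <- match(dp, table$dp)
  if (is.na(i)) {
    table <- rbind(table, data.frame(dp = as.integer(dp), eed = NA_real_,
                                     rg = NA_real_, source = NA_character_))
    i <- nrow(table)
  }
  if (!is.na(eed)) table$eed[i] <- eed
  if (!is.na(rg)) table$rg[i] <- rg
  table$source[i] <- source
  table[order(table$dp), , drop = FALSE]
}

#' Weight / kappa calibration sweep
#'
#' The empirical calibration protocol: for each named weight family, the
#' weight is varied over `weight_values` (default 1 to 10 in steps of 1)
#' while every other weight stays at 1, crossed with the `kappas` grid
#' (default the eleven values 0.0 to 1.0 in steps of 0.1) and with each
#' chain length in `dp_list`.  One Langevin simulation is run per cell (per
#' replicate) from the extended conformation and the post-equilibration mean
#' end-to-end distance and radius of gyration are scored as percentage
#' errors against the reference table.
#'
#' Chain lengths without a reference entry are skipped with a warning.
#' Replicates (`reps > 1`) rerun each cell with distinct seeds and average
#' the stochastic observables.
#'
#' @param dp_list Integer vector of chain lengths.
#' @param params [cg_params()].
#' @param base_config [run_config()] template; its `n_steps`,
#'   `snapshot_stride`, `dt`, `temperature`, `friction` and `seed` are used
#'   (per-cell seeds are derived deterministically from `base_config$seed`).
#' @param weight_families Character vector of weight names to vary
#'   (default `"eel"`).
#' @param weight_values Weight grid (default `1:10`).
#' @param kappas Screening-factor grid (default [kappa_grid()]).
#' @param reference Reference table (default [reference_table()]).
#' @param reps Replicates per cell (default 1, as in the production sweep).
#' @param equilibration Fraction of frames discarded before averaging.
#' @return A data.frame of calibration cells: `family`, `weight`, `kappa`,
#'   `dp`, `mean_eed`, `mean_rg`, `pe_eed`, `pe_rg`, `eed_direction`,
#'   `rg_direction`, `seed`.
#' @export
sweep_calibration <- function(dp_list, params, base_config,
                              weight_families = "eel",
                              weight_values = 1:10,
                              kappas = kappa_grid(),
                              reference = reference_table(),
                              reps = 1, equilibration = 0.1) {
  stopifnot(all(weight_families %in% energy_term_names()))
  cells <- list()
  cell_id <- 0L
  for (dp in dp_list) {
    ref <- reference[match(dp, reference$dp), ]
    if (nrow(ref) == 0L || is.na(ref$eed)) {
      warning("no reference EED for dp ", dp, "; skipping", call. = FALSE)
      next
    }
    chain <- build_chain(dp, params)
    for (fam in weight_families) {
      for (w in weight_values) {
        for (kap in kappas) {
          cell_id <- cell_id + 1L
          eeds <- rgs <- numeric(reps)
          seeds <- integer(reps)
          for (rep_i in seq_len(reps)) {
            seed <- (base_config$seed + 7919L * cell_id + rep_i) %% .Machine$integer.max
            seeds[rep_i] <- seed
            wts <- default_weights()
            wts[[fam]] <- w
            cfg <- run_config(n_steps = base_config$n_steps,
                              dt = base_config$dt,
                              temperature = base_config$temperature,
                              friction = base_config$friction,
                              seed = seed,
                              snapshot_stride = base_config$snapshot_stride,
                              weights = wts, kappa = kap,
                              init_velocities = base_config$init_velocities,
                              remove_com = base_config$remove_com)
            traj <- run_simulation(chain, params, cfg)
            obs <- observable_series(traj, equilibration = equilibration)
            eeds[rep_i] <- obs$mean_eed
            rgs[rep_i] <- obs$mean_rg
          }
          mean_eed <- mean(eeds)
          mean_rg <- mean(rgs)
          pe_e <- percentage_error(mean_eed, ref$eed)
          pe_r <- if (!is.na(ref$rg)) percentage_error(mean_rg, ref$rg) else
            data.frame(pe = NA_real_, direction = NA_character_)
          cells[[length(cells) + 1L]] <- data.frame(
            family = fam, weight = w, kappa = kap, dp = dp,
            mean_eed = mean_eed, mean_rg = mean_rg,
            pe_eed = pe_e$pe, pe_rg = pe_r$pe,
            eed_direction = pe_e$direction, rg_direction = pe_r$direction,
            seed = seeds[1L], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(cells)) {
    return(data.frame(family = character(0), weight = numeric(0),
                      kappa = numeric(0), dp = integer(0),
                      mean_eed = numeric(0), mean_rg = numeric(0),
                      pe_eed = numeric(0), pe_rg = numeric(0),
                      eed_direction = character(0), rg_direction = character(0),
                      seed = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, cells)
}

#' Rank calibration cells by percentage error
#'
#' Ascending total order on the chosen metric with a deterministic
#' tie-break: lower kappa first, then lower weight.
#'
#' @param cells Data.frame from [sweep_calibration()].
#' @param metric `"eed"` or `"rg"`.
#' @param top_n Number of rows to return (default 10).
#' @return The best `top_n` cells, ranked.
#' @export
rank_combinations <- function(cells, metric = c("eed", "rg"), top_n = 10) {
  metric <- match.arg(metric)
  if (!nrow(cells)) stop("no calibration cells to rank", call. = FALSE)
  pe <- cells[[paste0("pe_", metric)]]
  ord <- order(pe, cells$kappa, cells$weight)
  out <- cells[ord, , drop = FALSE]
  utils::head(out, top_n)
}

#' The three production parameter combinations
#'
#' Named weight/kappa combinations selected by the calibration for short,
#' medium and long chains: kappa 0.2 with the electrostatic weight at 7,
#' kappa 0.7 with the electrostatic weight at 7, and kappa 0.7 with the
#' virtual-bond-stretching weight at 4; all other weights stay at 1.
#'
#' @return A named list of three lists, each with `kappa` and `weights`.
#' @export
preset_combinations <- function() {
  mk <- function(kappa, term, value) {
    w <- default_weights()
    w[[term]] <- value
    list(kappa = kappa, weights = w)
  }
  list(
    kappa2_weel7 = mk(0.2, "eel", 7),
    kappa7_weel7 = mk(0.7, "eel", 7),
    kappa7_wbond4 = mk(0.7, "bond", 4)
  )
}
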