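# Eyring parameters consistent with a preset's rate at its own temperature,
# given an assumed activation enthalpy: dS is solved from
# ln k = ln(kB T / h) + dS/R' - dH/(R T).
eyring_params_for_preset <- function(preset, dH) {
  stopifnot(inherits(preset, "release_preset"))
  T <- preset$temperature
  if (is.na(T)) stop("preset has no temperature", call. = FALSE)
  co <- opsin_constants
  dS <- co$R_cal * (log(preset$k) - log(co$kB * T / co$h) +
                      dH / (co$R_kcal * T))
  eyring_params(dH, dS)
}

#' Run the full decay-analysis chain on presets
#'
#' Chains every kinetic stage on synthetic data generated from the given
#' presets: (i) a retinal-release trace is simulated, baseline-subtracted and
#' refit to recover the half-life; (ii) a rate-temperature series consistent
#' with each preset's rate (at an assumed common activation enthalpy) is
#' generated and subjected to Arrhenius and Eyring analysis; (iii) where a
#' matching H2O/D2O preset pair exists, the solvent KIE is computed and a
#' proton-inventory series is generated and classified as single- vs
#' two-site. The run is deterministic given `seed`.
#'
#' @param presets List of [release_preset()] objects (default: the three
#'   shipped samples Rho_WT, GCO_WT, GCO_E102Q).
#' @param seed Integer seed governing all noise draws.
#' @param noise_sd Trace noise as a fraction of amplitude (0 = noiseless).
#' @param rate_rel_noise Multiplicative (log-scale) noise on the
#'   temperature-series rates.
#' @param inventory_noise_sd Noise on inventory relative rates.
#' @param dH_assumed Common activation enthalpy used to construct the
#'   temperature series, kcal/mol (default 20, typical of visual-opsin
#'   meta II decay).
#' @param temps Temperature offsets (K) around each preset's own temperature
#'   for the thermo stage.
#' @param n_fracs D2O atom fractions for the inventory stage.
#' @param d2o_pairs Named list mapping a preset label to its
#'   `c(h2o = , d2o = )` half-life preset labels; defaults to the shipped
#'   GCO_WT and GCO_E102Q pairs.
#' @return An object of class `"decay_report"`: a data.frame with one row
#'   per sample (half-life, rate, Ea, dH, dS, dG298, KIE, inventory model)
#'   with the full per-stage fits in `attr(, "stages")` and the seed in
#'   `attr(, "seed")`.
#' @export
#' @examples
#' rep <- run_decay_analysis(seed = 1)
#' rep[, c("label", "t_half_s", "dG298_kcal_mol")]
run_decay_analysis <- function(presets = NULL, seed = 1, noise_sd = 0,
                               rate_rel_noise = 0, inventory_noise_sd = 0,
                               dH_assumed = 20,
                               temps = seq(-5, 5, length.out = 5),
                               n_fracs = seq(0, 1, length.out = 7),
                               d2o_pairs = NULL) {
  all_presets <- opsin_presets()
  if (is.null(presets)) {
    presets <- all_presets[c("Rho_WT", "GCO_WT", "GCO_E102Q")]
  }
  if (length(presets) == 0L) stop("no presets configured", call. = FALSE)
  if (is.null(d2o_pairs)) {
    d2o_pairs <- list(
      GCO_WT = c(h2o = "GCO_WT_H2O", d2o = "GCO_WT_D2O"),
      GCO_E102Q = c(h2o = "GCO_E102Q_H2O", d2o = "GCO_E102Q_D2O")
    )
  }
  stages <- list()
  rows <- lapply(seq_along(presets), function(i) {
    p <- presets[[i]]
    sub_seed <- seed + 1000L * i

    # stage 1: trace -> half-life
    pp <- p
    pp$noise_sd <- noise_sd * p$amplitude
    dt <- max(p$t_half / 40, 0.5)
    times <- seq(0, p$t_hv + 6 * p$t_half, by = dt)
    tr <- generate_release_trace(pp, times, seed = sub_seed)
    fit <- fit_monoexponential(subtract_dark_baseline(tr))

    # stage 2: temperature series -> Arrhenius/Eyring
    ep <- eyring_params_for_preset(p, dH_assumed)
    pts <- generate_temperature_series(ep, p$temperature + temps,
                                       rel_noise = rate_rel_noise,
                                       seed = sub_seed + 1L)
    ef <- eyring_fit(pts)
    af <- arrhenius_fit(pts)

    # stage 3: solvent isotope / proton inventory
    kie <- NA_real_
    inv_model <- NA_character_
    inv <- NULL
    pair <- d2o_pairs[[p$label]]
    if (!is.null(pair) && all(pair %in% names(all_presets))) {
      th_h <- all_presets[[pair[["h2o"]]]]$t_half
      th_d <- all_presets[[pair[["d2o"]]]]$t_half
      kie <- solvent_kie(th_h, th_d, mode = "half_lives")
      gb <- gross_butler_params(rate_from_half_life(th_h), 1 / kie)
      inv_pts <- generate_proton_inventory_series(
        gb, n_fracs, noise_sd = inventory_noise_sd, seed = sub_seed + 2L)
      inv <- select_inventory_model(inv_pts)
      inv_model <- inv$selected
    }

    stages[[p$label]] <<- list(trace_fit = fit, eyring = ef, arrhenius = af,
                               inventory = inv)
    data.frame(label = p$label,
               t_half_s = fit$t_half,
               k_per_s = fit$k,
               Ea_kcal_mol = af$Ea,
               dH_kcal_mol = ef$dH,
               dS_cal_mol_K = ef$dS,
               dG298_kcal_mol = ef$dG298,
               kie = kie,
               inventory_model = inv_model,
               converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "stages") <- stages
  attr(out, "seed") <- seed
  class(out) <- c("decay_report", "data.frame")
  out
}

#' @export
print.decay_report <- function(x, digits = 4, ...) {
  cat("Active-state decay analysis (seed", attr(x, "seed"), ")\n")
  df <- as.data.frame(x)
  df[] <- lapply(df, function(cl) if (is.numeric(cl)) signif(cl, digits)
                 else cl)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Run the structure-analysis chain
#'
#' Computes a ligand-cavity volume report from a structure (path or
#' [opsin_structure()]) and/or turns externally supplied net cavity volumes
#' into water capacities.
#'
#' @param struct A structure file path or an [opsin_structure()] containing
#'   the ligand; `NULL` to skip cavity detection.
#' @param ligand Ligand residue name in the structure (or an
#'   [opsin_structure()]); see [cavity_report()].
#' @param grid A [grid_spec()].
#' @param net_volumes Optional named numeric vector of net cavity volumes
#'   (A^3) to convert to water capacities.
#' @param reference An optional second structure (path or object) to
#'   superpose onto `struct` for an RMSD readout.
#' @param selections Optional named residue ranges passed to [kabsch_rmsd()].
#' @return A list of class `"structure_report"` with any of `cavity`
#'   (a [cavity_report()]), `water_capacity` (data.frame of volume and
#'   count), and `superposition` (a [kabsch_rmsd()] result).
#' @export
#' @examples
#' run_structure_analysis(net_volumes = c(GCO_WT = 1454.3, bRho_WT = 842.4))
run_structure_analysis <- function(struct = NULL, ligand = "LIG",
                                   grid = grid_spec(), net_volumes = NULL,
                                   reference = NULL, selections = NULL) {
  out <- list()
  if (!is.null(struct)) {
    if (is.character(struct)) struct <- read_structure(struct)
    out$cavity <- cavity_report(struct, ligand = ligand, grid = grid)
  }
  if (!is.null(net_volumes)) {
    out$water_capacity <- data.frame(
      label = names(net_volumes) %||% seq_along(net_volumes),
      v_net_A3 = as.numeric(net_volumes),
      n_water = water_capacity(as.numeric(net_volumes)),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(reference)) {
    if (is.character(reference)) reference <- read_structure(reference)
    out$superposition <- kabsch_rmsd(struct, reference,
                                     selections = selections)
  }
  if (length(out) == 0L) {
    stop("nothing to do: supply a structure, net volumes, or a reference",
         call. = FALSE)
  }
  class(out) <- "structure_report"
  out
}

#' @export
print.structure_report <- function(x, ...) {
  if (!is.null(x$cavity)) print(x$cavity)
  if (!is.null(x$water_capacity)) {
    cat("Water capacities:\n")
    print(x$water_capacity, row.names = FALSE)
  }
  if (!is.null(x$superposition)) print(x$superposition)
  invisible(x)
}
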