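#' Default run configuration
#'
#' Builds the full configuration for a simulation run: zone geometry, the
#' signal registry (diffusion and evaporation constants per signal, and the
#' zones each signal lives in), portal signal routes and entry conditions,
#' initial agent counts, and every rule constant of the agent state machines.
#'
#' The default geometry fixes the three zone areas at 12321, 2500 and 62500
#' lattice cells (111^2, 50^2, 250^2), approximating the ~1000:200:5000
#' volume ratios of an organ, the secondary lymphoid tissue and the blood.
#' The default initial condition uses 200 Dendritic Agents, the near-optimal
#' condition for mostly-win outcomes with enough losses for comparison.
#' The remaining counts and rule constants are this package's reconstruction
#' of a plausible parameter panel; see the methods vignette for the
#' rationale behind each default and for which published regularities they
#' were calibrated against.
#'
#' @param ... named overrides applied on top of the defaults.  Top-level
#'   entries (`stop_tick`, `seed`, ...) are replaced wholesale; entries of
#'   the `pars` vector and the `counts`/`specific` vectors can be overridden
#'   individually by passing, e.g., `pars = c(nk_kill_p = 0.8)` or
#'   `counts = c(Dendritic = 100)`.
#' @return a list of class `immunet_config`.
#' @examples
#' cfg <- default_config(stop_tick = 201L, seed = 42L)
#' cfg$zones$side
#' @export
default_config <- function(...) {
  cfg <- list(
    scenario = "viral",
    seed = 1L,
    stop_tick = 1001L,
    checkpoint_interval = 100L,
    zones = list(side = c(111L, 50L, 250L), pc_block_side = 71L),
    counts = c(Dendritic = 200L, Macrophage = 100L, NaturalKiller = 35L,
               Granulocyte = 100L, TCell = 200L, BCell = 200L, CTL = 50L),
    specific = c(TCell = 5L, BCell = 5L, CTL = 5L),
    dc_presenting_z2 = 0L,
    signals = data.frame(
      name = c("Virus", "PK1", "CK_pro", "CK_anti", "CH_tissue", "CH_lymph",
               "Ab1", "Ab2", "Ab5"),
      D = c(0.40, 0.80, 0.60, 0.60, 0.80, 0.85, 0.90, 0.90, 0.90),
      e = c(0.90, 0.98, 0.95, 0.95, 0.995, 0.997, 0.99, 0.99, 0.99),
      z1 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
      z2 = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
      z3 = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE),
    portal_routes = data.frame(
      signal = c("CH_tissue", "Ab1", "Ab2", "Ab5", "Ab1", "Ab2", "Ab5"),
      from = c(1L, 2L, 2L, 2L, 3L, 3L, 3L),
      to = c(3L, 3L, 3L, 3L, 1L, 1L, 1L),
      # antibodies re-entering the tissue arrive via capillaries everywhere
      mode = c("portal", "perfuse", "perfuse", "perfuse",
               "perfuse", "perfuse", "perfuse"),
      stringsAsFactors = FALSE),
    portal_entry = data.frame(
      zone = 1:3,
      signal = c("CH_tissue", NA, NA),
      threshold = c(0.005, 0, 0),
      stringsAsFactors = FALSE),
    pars = c(
      # parenchymal / infection dynamics
      theta_inf = 1.0, virus_dep = 2.1, pk1_dep = 1.0,
      ch_tissue_dep_pc = 2.0, L_lyse = 20, stress_recover = 5,
      d_regen = 10, k_regen = 2, infect_p = 0.45, init_virus = 6.0,
      # movement / fields
      chemo_threshold = 0.005, floor_eps = 1e-6, portal_frac = 0.2,
      # dendritic agents
      dc_sense_radius = 2, dc_act_lifespan = 300, dc_imm_lifespan = 1200,
      dc_influx = 0.6, dc_influx_cap = 6.0, dc_crowd_min = 4, dc2_pk1_max = 0.01, chl_dep_dc = 2.0,
      # macrophages
      mac_pk1_thresh = 0.5, mac_kill_p = 0.5, mac_lifespan = 1500,
      mac_capacity = 2, mac_digest = 30,
      m1_ckpro_dep = 0.5, m1_ch_dep = 0.5, m2_ckanti_dep = 1.0,
      # natural killers
      nk_kill_p = 0.6, nk_ckanti_thresh = 0.5, nk_lifespan = 1500,
      nk_capacity = 8,
      # granulocytes
      gran_pk1_thresh = 1.5, gran_burst = 10, gran_kill_p = 0.8,
      gran_ckpro_dep = 0.5, gran_lifespan = 1500,
      # lymphocytes
      prolif_cap = 17, division_interval = 1, treg_frac = 0.1,
      class_switch = 30, t_eff_lifespan = 150, plasma_lifespan = 250,
      naive_lifespan = 1500, memory_lifespan = 2000,
      eff_ck_dep = 0.5, eff_ch_dep = 0.5, ab_dep = 29.0, ab_neut = 1.5,
      ctl_kill_p = 1.0,
      # resolution / housekeeping
      corpse_decay = 30, resolution_lag = 20, memory_conv_p = 0.2)
  )
  class(cfg) <- "immunet_config"
  modify_config(cfg, ...)
}

#' Modify a configuration
#'
#' @param config an `immunet_config`.
#' @param ... named overrides (see [default_config()]).
#' @return the modified configuration.
#' @export
modify_config <- function(config, ...) {
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% c("pars", "counts", "specific")) {
      v <- ov[[nm]]
      stopifnot(!is.null(names(v)))
      bad <- setdiff(names(v), names(config[[nm]]))
      if (length(bad))
        stop("unknown ", nm, " entries: ", paste(bad, collapse = ", "))
      config[[nm]][names(v)] <- v
    } else if (nm == "zones") {
      config$zones[names(ov[[nm]])] <- ov[[nm]]
    } else {
      if (!nm %in% names(config)) stop("unknown config entry: ", nm)
      config[[nm]] <- ov[[nm]]
    }
  }
  validate_config(config)
}

#' Validate a configuration
#'
#' Checks zone geometry, agent counts against free cells, signal constants
#' and scenario flags; called by [modify_config()] and [run()].
#'
#' @param config an `immunet_config`.
#' @return the configuration, invisibly usable, or an error.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "immunet_config") || is.list(config))
  side <- config$zones$side
  if (length(side) != 3L || any(side < 3L))
    stop("three zone side lengths >= 3 are required")
  bs <- config$zones$pc_block_side
  if (bs < 4L || bs > side[1] - 2L)
    stop("pc_block_side must fit inside zone 1 with a one-cell margin")
  if (bs^2 < 1L) stop("at least one Parenchymal Agent is required")
  if (!config$scenario %in% c("viral", "bacterial"))
    stop("scenario must be 'viral' or 'bacterial'")
  if (config$stop_tick < config$checkpoint_interval)
    stop("stop_tick must be >= checkpoint_interval")
  with(config$signals, {
    if (any(D <= 0 | D > 1 | e <= 0 | e > 1))
      stop("signal D and e must lie in (0, 1]")
  })
  n_z1 <- sum(config$counts[c("Dendritic", "Macrophage", "NaturalKiller",
                              "Granulocyte")])
  n_z2 <- sum(config$counts[c("TCell", "BCell", "CTL")]) +
    config$dc_presenting_z2
  if (n_z1 > side[1]^2 - 4L) stop("zone 1 agent counts exceed free cells")
  if (n_z2 > side[2]^2 - 4L) stop("zone 2 agent counts exceed free cells")
  if (any(config$specific > config$counts[c("TCell", "BCell", "CTL")]))
    stop("specific lymphocyte counts exceed the type totals")
  config
}

#' Read / write configurations as YAML or JSON
#'
#' The on-disk representation is plain structured text; the extension picks
#' the format (`.yml`/`.yaml` or `.json`).
#'
#' @param path file path.
#' @return `read_config()` returns an `immunet_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to read JSON configurations")
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_config()
  for (nm in intersect(names(raw), names(cfg))) {
    if (nm %in% c("pars", "counts", "specific")) {
      cfg[[nm]][names(raw[[nm]])] <- unlist(raw[[nm]])
    } else if (nm %in% c("signals", "portal_routes", "portal_entry")) {
      cfg[[nm]] <- as.data.frame(raw[[nm]], stringsAsFactors = FALSE)
    } else if (nm == "zones") {
      cfg$zones[names(raw$zones)] <- lapply(raw$zones, function(v)
        if (is.numeric(v)) as.integer(v) else v)
      cfg$zones$side <- as.integer(unlist(cfg$zones$side))
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @param config an `immunet_config` to serialise.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$counts <- as.list(obj$counts)
  obj$specific <- as.list(obj$specific)
  obj$pars <- as.list(obj$pars)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to write JSON configurations")
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}
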