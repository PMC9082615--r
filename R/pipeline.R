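#' Load and validate a pipeline configuration
#'
#' Reads a YAML pipeline configuration (or accepts an equivalent named
#' list). All physical constants must be explicit: in particular the neat
#' water-vapor surface tension `constants$gamma0` has no default, since its
#' value is specific to the water model or experiment being emulated.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated config list (class `surfwet_config`).
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  req <- function(x, what) {
    if (is.null(x)) stop("config is missing required entry: ", what,
                         call. = FALSE)
    x
  }
  req(config$constants, "constants")
  req(config$constants$gamma0, "constants$gamma0 (neat tension, mN/m)")
  req(config$constants$theta_deg, "constants$theta_deg")
  config$constants$T <- config$constants$T %||% 300
  config$seed <- config$seed %||% 1L
  structure(config, class = c("surfwet_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_meta <- function(path, params) {
  meta <- c(params, list(
    package = "surfwet",
    version = as.character(utils::packageVersion("surfwet")),
    created = "run"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the synthetic-data-to-droplet analysis pipeline
#'
#' Executes, in dependency order, the stages
#' `generate` (synthetic profiles, RDFs and isotherm series with known
#' ground truth), `adsorption` (dividing surface, bulk plateau and surface
#' excess from the generated profiles), `fit` (Langmuir/ODR fits for both
#' interfaces), `thermo` (KB integrals and the correction factor xi),
#' `tension` (surface-tension reduction curves), and `droplet`
#' (contact-angle change, full and linearized). Each stage writes its
#' artifact plus a `.meta.json` sidecar into `outdir`; a stage failure
#' halts the run with the failing stage named, retaining earlier outputs.
#' Reruns with the same config and seed are bit-identical.
#'
#' @param config a [load_config()] result, YAML path, or list.
#' @param outdir output directory (created if needed).
#' @param stages character vector of stages to run, or `"all"`.
#' @return invisible report list aggregating fitted (k_c, gamma_inf, K),
#'   xi, and the predicted delta-theta curve.
#' @export
run_pipeline <- function(config, outdir = tempfile("surfwet_run_"),
                         stages = "all") {
  cfg <- load_config(config)
  all_stages <- c("generate", "adsorption", "fit", "thermo", "tension",
                  "droplet")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  report <- list(outdir = outdir, seed = cfg$seed)
  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop(sprintf("input '%s' for stage '%s' not found", path, stage),
           call. = FALSE)
    }
    path
  }

  run_stage("generate", function() {
    g <- cfg$generate
    spec <- do.call(slab_spec, g$slab %||% list())
    truth <- do.call(surfactant_truth,
                     c(g$truth %||% list(), list(seed = cfg$seed)))
    prof <- make_slab_profiles(spec, truth, noise = g$profile_noise %||% 0)
    write_profile(prof$water, p("water_profile.dat"))
    write_profile(prof$surfactant, p("surfactant_profile.dat"))
    .write_meta(p("water_profile.dat"),
                list(stage = "generate", seed = cfg$seed,
                     slab = unclass(spec), truth = unclass(truth)))
    for (iface in c("v", "s")) {
      iso_cfg <- g[[paste0("isotherm_", iface)]]
      if (is.null(iso_cfg)) next
      ser <- make_isotherm_series(
        k_c = iso_cfg$k_c, gamma_inf = iso_cfg$gamma_inf,
        concentrations = unlist(iso_cfg$concentrations),
        noise_x = iso_cfg$noise_x %||% 0, noise_y = iso_cfg$noise_y %||% 0,
        seed = cfg$seed + (iface == "s"),
        interface = if (iface == "v") "water_vapor" else "solid_water")
      path <- p(sprintf("isotherm_%s.csv", iface))
      write_isotherm(ser, path)
      .write_meta(path, c(list(stage = "generate", seed = cfg$seed),
                          iso_cfg))
    }
    for (pair in c("mm", "mw")) {
      rd_cfg <- (g$rdf %||% list())[[pair]]
      if (is.null(rd_cfg)) next
      rdf <- make_rdf(do.call(rdf_spec, rd_cfg), pair = pair)
      path <- p(sprintf("rdf_%s.dat", pair))
      utils::write.table(data.frame(rdf$r, rdf$g), path,
                         row.names = FALSE, col.names = FALSE)
      .write_meta(path, c(list(stage = "generate"), rd_cfg))
    }
    report$generate <<- list(z0_true = attr(prof, "z0_true"),
                             gamma_true = truth$gamma_true)
  })

  run_stage("adsorption", function() {
    water <- read_profile(need(p("water_profile.dat"), "adsorption"))
    surf <- read_profile(need(p("surfactant_profile.dat"), "adsorption"))
    z0 <- gibbs_dividing_surface(water)
    bulk <- find_bulk(surf)
    gam <- excess_adsorption(surf, z0, bulk$c_bulk)
    res <- list(z0_nm = as.numeric(z0), c_bulk_nm3 = bulk$c_bulk,
                gamma_nm2 = gam)
    jsonlite::write_json(res, p("adsorption.json"), auto_unbox = TRUE,
                         digits = NA)
    .write_meta(p("adsorption.json"), list(stage = "adsorption"))
    report$adsorption <<- res
  })

  run_stage("fit", function() {
    fits <- list()
    for (iface in c("v", "s")) {
      path <- p(sprintf("isotherm_%s.csv", iface))
      if (!file.exists(path)) next
      ser <- read_isotherm(path, interface = if (iface == "v")
        "water_vapor" else "solid_water")
      fit <- fit_langmuir(ser, weighting = cfg$fit$weighting %||% "auto")
      fits[[iface]] <- fit
      flat <- list(k_c_nm3 = fit$k_c, gamma_inf_nm2 = fit$gamma_inf,
                   K_nm = fit$K, method = fit$method,
                   fit_window_mol_l = fit$fit_window, n_used = fit$n_used)
      jsonlite::write_json(flat, p(sprintf("fit_%s.json", iface)),
                           auto_unbox = TRUE, digits = NA)
      .write_meta(p(sprintf("fit_%s.json", iface)),
                  list(stage = "fit", interface = fit$interface))
    }
    report$fits <<- fits
  })

  run_stage("thermo", function() {
    fit_v <- report$fits$v
    if (is.null(fit_v)) stop("thermo stage needs the water-vapor fit")
    G <- list()
    for (pair in c("mm", "mw")) {
      path <- need(p(sprintf("rdf_%s.dat", pair)), "thermo")
      m <- utils::read.table(path)
      G[[pair]] <- as.numeric(kb_integral(list(r = m[[1]], g = m[[2]])))
    }
    th <- solution_thermo(G$mm, G$mw, gamma_inf = fit_v$gamma_inf,
                          K = fit_v$K, T = cfg$constants$T)
    jsonlite::write_json(unclass(th), p("thermo.json"), auto_unbox = TRUE,
                         digits = NA)
    .write_meta(p("thermo.json"), list(stage = "thermo"))
    report$thermo <<- th
  })

  run_stage("tension", function() {
    c0 <- unlist(cfg$droplet$c0_grid %||%
                   pretty(c(0, max(report$fits$v$fit_window)), 20))
    xi <- if (!is.null(report$thermo)) report$thermo$xi else 1
    for (iface in c("v", "s")) {
      fit <- report$fits[[iface]]
      if (is.null(fit)) next
      model <- tension_model(fit$gamma_inf, xi = if (iface == "v") xi else 1,
                             T = cfg$constants$T,
                             gamma0 = if (iface == "v")
                               cfg$constants$gamma0 else NA_real_)
      tab <- dgamma_of_c(c0, fit, model)
      lin <- dgamma_linear(tab$Gamma_nm2, model)
      bm <- if (!is.null(tab$beyond_model)) tab$beyond_model
            else rep(FALSE, nrow(tab))
      tab$validity_flag <- ifelse(bm, "beyond_model",
                                  ifelse(lin$linear_ok, "linear_ok",
                                         "nonlinear"))
      path <- p(sprintf("tension_%s.csv", iface))
      utils::write.csv(tab[c("c0_mol_l", "dgamma_mN_m", "pi_mN_m",
                             "validity_flag")], path, row.names = FALSE)
      .write_meta(path, list(stage = "tension", xi = model$xi))
      report[[paste0("tension_", iface)]] <<- tab
    }
  })

  run_stage("droplet", function() {
    fits <- report$fits
    if (is.null(fits$v) || is.null(fits$s)) {
      stop("droplet stage needs fits for both interfaces")
    }
    xi <- if (!is.null(report$thermo)) report$thermo$xi else 1
    c0 <- unlist(cfg$droplet$c0_grid %||% seq(0, 0.5, length.out = 26))
    st <- droplet_state(
      theta_deg = cfg$constants$theta_deg, gamma0 = cfg$constants$gamma0,
      c0_mol_l = c0,
      fit_v = fits$v,
      model_v = tension_model(fits$v$gamma_inf, xi = xi,
                              T = cfg$constants$T,
                              gamma0 = cfg$constants$gamma0),
      fit_s = fits$s,
      model_s = tension_model(fits$s$gamma_inf, xi = 1,
                              T = cfg$constants$T))
    full <- delta_theta_full(st)
    lin <- delta_theta_linear(st)
    out <- data.frame(c0_mol_l = c0, dtheta_deg = full$dtheta_deg,
                      dtheta_linear_deg = lin$dtheta_deg,
                      flag = full$flag)
    utils::write.csv(out, p("droplet_curve.csv"), row.names = FALSE)
    .write_meta(p("droplet_curve.csv"),
                list(stage = "droplet", theta_deg = cfg$constants$theta_deg))
    report$droplet <<- out
  })

  invisible(report)
}

#' Demo pipeline configuration
#'
#' Returns the path to the bundled demonstration configuration, a complete
#' synthetic end-to-end run at modest problem sizes.
#'
#' @return path to a YAML file.
#' @export
demo_config <- function() {
  system.file("extdata", "demo_config.yaml", package = "surfwet",
              mustWork = TRUE)
}
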