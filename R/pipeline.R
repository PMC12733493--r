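# Pipeline driver: solvent -> solute -> 3D solve -> hydration analysis,
# with input-digest caching and a run manifest.

#' Derive the hydration report from converged fields
#'
#' Runs the full analysis stage: distance transform, shell profile,
#' boundary detection, total hydration number, H-bond fraction, pocket
#' counts and SASA.
#'
#' @param fields A `solvation_fields` from [solve_rism3d()].
#' @param solute The [solute_system()] used for the solve.
#' @param bin Shell-profile bin, A (default: grid spacing).
#' @param r_cut Shell boundary override, A; by default located with
#'   [find_shell_boundary()].
#' @param pockets Optional list of [pocket_spec()] objects.
#' @param hbond_criterion Passed to [hbond_fraction()].
#' @param dist_mode `"center"` or `"surface"` distance definition.
#' @param sasa_probe,sasa_n_points SASA settings.
#' @param smooth Smooth the shell profile before boundary detection.
#' @return Object of class `hydration_report`.
#' @export
analyze_fields <- function(fields, solute, bin = NULL, r_cut = NULL,
                           pockets = NULL, hbond_criterion = list(),
                           dist_mode = "center", sasa_probe = 1.4,
                           sasa_n_points = 960L, smooth = FALSE) {
  grid <- fields$grid
  types <- fields$site_types
  o_site <- if ("Ow" %in% types) "Ow" else types[1]
  h_site <- if ("Hw" %in% types) "Hw" else NULL
  rho_mol <- fields$params$density
  rho_O <- unname(fields$rho_site[[o_site]])
  dist <- distance_transform(solute, grid, mode = dist_mode)
  profile <- shell_profile(fields$g[[o_site]], dist, rho_O, bin = bin,
                           smooth = smooth)
  weak <- NA
  if (is.null(r_cut)) {
    b <- find_shell_boundary(profile)
    r_cut <- b$r_cut
    weak <- b$weak
  }
  n_tot <- hydration_number(fields$g[[o_site]], dist, r_cut, rho_O)
  hb <- if (!is.null(h_site)) {
    hbond_fraction(fields$g[[h_site]], fields$g[[o_site]], solute, dist,
                   r_cut, rho_mol, criterion = hbond_criterion)
  } else NA_real_
  pk <- if (!is.null(pockets)) {
    v <- vapply(pockets, function(p)
      pocket_hydration(fields$g[[o_site]], dist, solute, p, r_cut, rho_O),
      0)
    names(v) <- vapply(pockets, `[[`, "", "name")
    v
  } else NULL
  sa <- sasa(solute, probe = sasa_probe, n_points = sasa_n_points)
  structure(
    list(shell_thickness_A = r_cut, shell_thickness_nm = r_cut / 10,
         n_total = n_tot,
         hbond_fraction = as.numeric(hb),
         pocket_counts = pk,
         sasa_A2 = sa$total,
         weak_shell = weak,
         residual = fields$residual,
         dist_mode = dist_mode,
         profile = profile),
    class = "hydration_report")
}

#' @export
print.hydration_report <- function(x, ...) {
  cat("<hydration_report>\n")
  cat(sprintf("  shell thickness : %.3f A (%.2f nm)%s\n", x$shell_thickness_A,
              x$shell_thickness_nm,
              if (isTRUE(x$weak_shell)) "  [weak shell]" else ""))
  cat(sprintf("  hydration number: %.1f\n", x$n_total))
  if (is.finite(x$hbond_fraction))
    cat(sprintf("  H-bond fraction : %.2f\n", x$hbond_fraction))
  if (!is.null(x$pocket_counts))
    for (nm in names(x$pocket_counts))
      cat(sprintf("  pocket %-9s: %.1f waters\n", nm, x$pocket_counts[[nm]]))
  cat(sprintf("  SASA            : %.2f A^2\n", x$sasa_A2))
  invisible(x)
}

#' @keywords internal
report_payload <- function(report) {
  list(shell_thickness_A = report$shell_thickness_A,
       shell_thickness_nm = report$shell_thickness_nm,
       n_total = report$n_total,
       hbond_fraction = report$hbond_fraction,
       pocket_counts = as.list(report$pocket_counts),
       sasa_A2 = report$sasa_A2,
       weak_shell = report$weak_shell,
       residual = report$residual,
       dist_mode = report$dist_mode)
}

#' Write a hydration report as JSON
#'
#' The payload contains no timestamps, so identical runs produce
#' byte-identical files.
#'
#' @param report A `hydration_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_payload(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Fills defaults and checks ranges; raises a validation error on a
#' malformed configuration.
#'
#' @param config List, or path to a YAML/JSON config file.
#' @return The completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config)
    else yaml::read_yaml(config)
  }
  defaults <- list(
    solvent = list(model = "mspce", catalogue = NULL, n_points = 8192L,
                   dr = 0.01, closure = "kh", tol = 1e-8, table = NULL),
    solute = list(pqr = NULL),
    grid = list(spacing = 0.25, buffer = 12),
    solver = list(closure = "kh", tol = 1e-6, n_vectors = 5L, damp = 0.7,
                  max_iter = 500L),
    analysis = list(bin = NULL, r_cut = NULL, pockets = NULL,
                    dist_mode = "center",
                    hbond = list(), sasa = list(probe = 1.4, n_points = 960L)),
    output = list(dir = "rismhydra-run", formats = "dx",
                  isovalues = c(2, 3, 4), write_fields = TRUE,
                  cache = TRUE))
  cfg <- utils::modifyList(defaults, config)
  # spacing/buffer may arrive as strings with nm/A suffixes
  cfg$grid$spacing <- parse_length(cfg$grid$spacing)
  cfg$grid$buffer <- parse_length(cfg$grid$buffer)
  if (!is.numeric(cfg$grid$spacing) || cfg$grid$spacing <= 0)
    stop("config validation error: grid.spacing must be > 0")
  if (cfg$grid$buffer <= 0)
    stop("config validation error: grid.buffer must be > 0")
  if (cfg$solver$tol <= 0 || cfg$solvent$tol <= 0)
    stop("config validation error: tolerances must be > 0")
  if (!cfg$solver$closure %in% c("kh", "hnc") ||
      !cfg$solvent$closure %in% c("kh", "hnc"))
    stop("config validation error: closure must be 'kh' or 'hnc'")
  if (is.null(cfg$solute$pqr))
    stop("config validation error: solute.pqr is required")
  cfg
}

# lengths in config may carry explicit unit suffixes ("0.025nm", "0.25A")
#' @keywords internal
parse_length <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(x)
  if (grepl("nm$", x)) return(as.numeric(sub("nm$", "", x)) * 10)
  if (grepl("A$", x)) return(as.numeric(sub("A$", "", x)))
  as.numeric(x)
}

#' Run the full hydration pipeline
#'
#' Executes solvent susceptibility -> solute preparation -> 3D solve ->
#' analysis, caching the solvent and solve stages by input digest under
#' `output.dir/cache` so unchanged reruns are instant and
#' byte-identical.
#'
#' @param config List or config file path; see [validate_config()].
#' @return List: `report` (a `hydration_report`), `fields`, `solute`,
#'   `manifest`, `paths` (written files).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  out <- cfg$output$dir
  dir.create(file.path(out, "cache"), recursive = TRUE, showWarnings = FALSE)
  cache_get <- function(key) {
    f <- file.path(out, "cache", paste0(key, ".rds"))
    if (cfg$output$cache && file.exists(f)) readRDS(f) else NULL
  }
  cache_put <- function(key, val) {
    if (cfg$output$cache)
      saveRDS(val, file.path(out, "cache", paste0(key, ".rds")))
    val
  }

  # -- solvent stage
  if (!is.null(cfg$solvent$table)) {
    chi <- read_susceptibility(cfg$solvent$table)
    skey <- rlang::hash(list("table", unname(tools::md5sum(cfg$solvent$table))))
  } else {
    model <- solvent_catalogue(cfg$solvent$model, file = cfg$solvent$catalogue)
    skey <- rlang::hash(list("solvent", model, cfg$solvent$n_points,
                             cfg$solvent$dr, cfg$solvent$closure,
                             cfg$solvent$tol))
    chi <- cache_get(skey)
    if (is.null(chi)) {
      chi <- solve_rism1d(model,
                          radial_grid(cfg$solvent$n_points, cfg$solvent$dr),
                          closure = cfg$solvent$closure,
                          options = list(tol = cfg$solvent$tol))
      cache_put(skey, chi)
    }
  }

  # -- solute stage
  solute <- read_pqr(cfg$solute$pqr)
  sol_digest <- unname(tools::md5sum(cfg$solute$pqr))

  # -- 3D solve stage
  fkey <- rlang::hash(list("solve", skey, sol_digest, cfg$grid, cfg$solver))
  fields <- cache_get(fkey)
  if (is.null(fields)) {
    fields <- solve_rism3d(solute, chi,
                           buffer = cfg$grid$buffer,
                           spacing = cfg$grid$spacing,
                           closure = cfg$solver$closure,
                           tol = cfg$solver$tol,
                           max_iter = cfg$solver$max_iter,
                           n_vectors = cfg$solver$n_vectors,
                           damp = cfg$solver$damp)
    cache_put(fkey, fields)
  }

  # -- analysis stage
  pockets <- if (!is.null(cfg$analysis$pockets)) {
    if (is.character(cfg$analysis$pockets)) sudlow_sites(cfg$analysis$pockets)
    else cfg$analysis$pockets
  } else NULL
  report <- analyze_fields(fields, solute,
                           bin = cfg$analysis$bin,
                           r_cut = cfg$analysis$r_cut,
                           pockets = pockets,
                           hbond_criterion = cfg$analysis$hbond,
                           dist_mode = cfg$analysis$dist_mode,
                           sasa_probe = cfg$analysis$sasa$probe,
                           sasa_n_points = cfg$analysis$sasa$n_points)

  paths <- character(0)
  if (isTRUE(cfg$output$write_fields))
    paths <- write_volumetric(fields, out, format = cfg$output$formats,
                              solute = solute)
  rp <- file.path(out, "report.json")
  write_report(report, rp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rismhydra")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = cfg[setdiff(names(cfg), "output")],
    solute_digest = sol_digest,
    solvent_key = skey,
    grid = list(shape = fields$grid$shape, origin = fields$grid$origin,
                spacing = fields$grid$spacing),
    residual_trace = fields$trace,
    iterations = fields$iterations,
    isovalues = cfg$output$isovalues)
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  list(report = report, fields = fields, solute = solute,
       manifest = manifest, paths = c(paths, rp, mp))
}
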