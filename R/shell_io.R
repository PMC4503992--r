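# Shared I/O: unit-suffixed CSV dialects with provenance headers, pipeline
# configuration, and the command-line entry point.

provenance_header <- function(seed = NULL, config_hash = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("cytomech")),
                  error = function(e) "dev")
  h <- c(sprintf("# tool: cytomech %s", ver))
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %s", seed))
  if (!is.null(config_hash)) h <- c(h, sprintf("# config_hash: %s", config_hash))
  h
}

write_csv_prov <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config_hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

check_numeric_cols <- function(df, cols, path) {
  for (cc in cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s' of %s (data row %d)",
                   cc, path, ifelse(is.na(bad), 1L, bad)))
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s' of %s (data row %d)",
                   cc, path, which(is.na(v))[1]))
    }
  }
}

#' Write / read a displacement field as CSV
#'
#' Long-format CSV with unit-suffixed columns `x_um`, `y_um`, `ux_um`,
#' `uy_um` and a `#`-prefixed provenance header.  Reading detects whether
#' the points form the complete regular grid: if so a
#' [displacement_field()] is returned, otherwise the scattered points are
#' returned (flagged for interpolation with [interp_displacements()]).
#'
#' @param field A [displacement_field()].
#' @param path CSV path.
#' @param seed Optional seed recorded in the provenance header.
#' @return `write_displacement_csv`: the path, invisibly.
#'   `read_displacement_csv`: a `displacement_field`, or a data frame of
#'   scattered points with attribute `scattered = TRUE`.
#' @export
write_displacement_csv <- function(field, path, seed = NULL) {
  stopifnot(inherits(field, "displacement_field"))
  xy <- grid_xy(field$grid)
  df <- data.frame(x_um = as.vector(xy$x), y_um = as.vector(xy$y),
                   ux_um = as.vector(field$ux), uy_um = as.vector(field$uy))
  write_csv_prov(df, path, seed = seed)
}

#' @rdname write_displacement_csv
#' @export
read_displacement_csv <- function(path) {
  df <- read_csv_prov(path)
  req <- c("x_um", "y_um", "ux_um", "uy_um")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("no data rows in ", path)
  check_numeric_cols(df, req, path)
  grid <- infer_grid(df$x_um, df$y_um)
  if (is.null(grid)) {
    attr(df, "scattered") <- TRUE
    return(df)
  }
  ord <- order(df$x_um, df$y_um)   # column-major: y fastest within x
  displacement_field(grid,
                     matrix(df$ux_um[ord], grid$shape[1], grid$shape[2]),
                     matrix(df$uy_um[ord], grid$shape[1], grid$shape[2]))
}

infer_grid <- function(x, y) {
  ux <- sort(unique(x)); uy <- sort(unique(y))
  if (length(ux) < 2 || length(uy) < 2) return(NULL)
  if (length(ux) * length(uy) != length(x)) return(NULL)
  dx <- diff(ux); dy <- diff(uy)
  tol <- 1e-6 * max(dx[1], dy[1])
  if (max(abs(dx - dx[1])) > tol || max(abs(dy - dy[1])) > tol) return(NULL)
  if (abs(dx[1] - dy[1]) > tol) return(NULL)
  grid_spec(dx[1], c(length(uy), length(ux)), origin = c(ux[1], uy[1]))
}

#' Write / read a traction field as CSV
#'
#' Columns `x_um`, `y_um`, `tx_Pa`, `ty_Pa`.
#'
#' @param field A [traction_field()].
#' @param path CSV path.
#' @param seed Optional provenance seed.
#' @export
write_traction_csv <- function(field, path, seed = NULL) {
  stopifnot(inherits(field, "traction_field"))
  xy <- grid_xy(field$grid)
  df <- data.frame(x_um = as.vector(xy$x), y_um = as.vector(xy$y),
                   tx_Pa = as.vector(field$tx), ty_Pa = as.vector(field$ty))
  write_csv_prov(df, path, seed = seed)
}

#' @rdname write_traction_csv
#' @export
read_traction_csv <- function(path) {
  df <- read_csv_prov(path)
  req <- c("x_um", "y_um", "tx_Pa", "ty_Pa")
  if (!all(req %in% names(df)))
    stop("missing column(s) in ", path, ": ",
         paste(setdiff(req, names(df)), collapse = ", "))
  if (nrow(df) == 0) stop("no data rows in ", path)
  check_numeric_cols(df, req, path)
  grid <- infer_grid(df$x_um, df$y_um)
  if (is.null(grid)) stop("traction CSV must contain a complete regular grid")
  ord <- order(df$x_um, df$y_um)
  traction_field(grid,
                 matrix(df$tx_Pa[ord], grid$shape[1], grid$shape[2]),
                 matrix(df$ty_Pa[ord], grid$shape[1], grid$shape[2]))
}

#' Write / read a cell contour as CSV
#'
#' Closed-polygon vertex list, columns `x_um`, `y_um`.
#'
#' @param mask A [cell_mask()] with a polygon.
#' @param path CSV path.
#' @export
write_mask_csv <- function(mask, path) {
  stopifnot(inherits(mask, "cell_mask"))
  if (is.null(mask$polygon)) stop("mask has no polygon to write")
  write_csv_prov(data.frame(x_um = mask$polygon[, 1],
                            y_um = mask$polygon[, 2]), path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  df <- read_csv_prov(path)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop("contour CSV needs columns x_um, y_um")
  check_numeric_cols(df, c("x_um", "y_um"), path)
  cell_mask(polygon = cbind(df$x_um, df$y_um))
}

#' Write / read microtubule traces as CSV
#'
#' Long format: `cell_id`, `mt_id`, `frame`, `length_um`,
#' `frame_interval_s`.
#'
#' @param traces List of [mt_trace()] objects.
#' @param path CSV path.
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.frame(cell_id = tr$cell_id, mt_id = tr$mt_id,
               frame = seq_along(tr$lengths), length_um = tr$lengths,
               frame_interval_s = tr$frame_interval))
  write_csv_prov(do.call(rbind, rows), path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- read_csv_prov(path)
  req <- c("cell_id", "mt_id", "frame", "length_um", "frame_interval_s")
  if (!all(req %in% names(df)))
    stop("trace CSV needs columns ", paste(req, collapse = ", "))
  check_numeric_cols(df, c("frame", "length_um", "frame_interval_s"), path)
  sp <- split(df, df$mt_id)
  unname(lapply(sp, function(d) {
    d <- d[order(d$frame), ]
    mt_trace(d$length_um, frame_interval = d$frame_interval_s[1],
             cell_id = d$cell_id[1], mt_id = d$mt_id[1])
  }))
}

#' Read and validate a pipeline configuration
#'
#' YAML or JSON (by file extension).  Unknown top-level or per-stage keys
#' are rejected before anything runs.
#'
#' @param path Config file (.yaml/.yml/.json).
#' @return Named list with class `pipeline_config` and a `config_hash`
#'   attribute (md5 of the canonicalized content).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("config must be .yaml/.yml/.json"))
  known_top <- c("seed", "out_dir", "stages", "tfm", "metrics")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  known_tfm <- c("gel_kpa", "nu", "lambda", "grid_n", "grid_spacing_um",
                 "noise_sd_um", "n_dipoles", "force_pN", "separation_um",
                 "patch_radius_um")
  if (!is.null(cfg$tfm)) {
    unknown <- setdiff(names(cfg$tfm), known_tfm)
    if (length(unknown) > 0)
      stop("unknown tfm config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$seed) && cfg$seed != round(cfg$seed))
    stop("seed must be an integer")
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE)
  attr(cfg, "config_hash") <- unname(tools::md5sum(tmp))
  unlink(tmp)
  class(cfg) <- c("pipeline_config", class(cfg))
  cfg
}

pipeline_defaults <- function() {
  list(seed = 1, out_dir = ".",
       stages = c("simulate", "invert", "metrics"),
       tfm = list(gel_kpa = 11, nu = 0.5, lambda = 1e-3, grid_n = 32,
                  grid_spacing_um = 2, noise_sd_um = 0.005, n_dipoles = 1,
                  force_pN = 100, separation_um = 20, patch_radius_um = 4))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the simulate -> invert -> metrics pipeline
#'
#' Executes the configured stages in order, writing provenance-stamped
#' CSV artifacts (displacements, recovered tractions, per-cell metrics)
#' under `out_dir`.  Fully deterministic given (config, seed).
#'
#' @param config A [read_pipeline_config()] result, a config list, or a
#'   path to a config file.  Missing entries fall back to defaults.
#' @param quiet Suppress INFO logging.
#' @return Invisibly, a list with the artifact paths and the per-cell
#'   metrics data frame; an error in any stage aborts with the stage named.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- merge_config(pipeline_defaults(), config)
  hash <- attr(config, "config_hash") %||% "defaults"
  info <- function(...) if (!quiet) message("[cytomech] ", sprintf(...))
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  artifacts <- list()
  stage <- "simulate"
  result <- tryCatch({
    tf <- cfg$tfm
    gel <- gel_substrate(tf$gel_kpa * 1e3, tf$nu)
    grid <- grid_spec(tf$grid_spacing_um, c(tf$grid_n, tf$grid_n))
    info("stage simulate: %d dipole(s), %g kPa gel, %dx%d grid, seed %d",
         tf$n_dipoles, tf$gel_kpa, tf$grid_n, tf$grid_n, seed)
    ext <- tf$grid_n * tf$grid_spacing_um
    set.seed(seed)
    dips <- lapply(seq_len(tf$n_dipoles), function(i)
      dipole_spec(center = stats::runif(2, 0.35, 0.65) * ext,
                  axis_angle = stats::runif(1, 0, pi),
                  force_magnitude = tf$force_pN,
                  separation = tf$separation_um,
                  patch_radius = tf$patch_radius_um))
    scene <- simulate_traction_scene(dips, gel, grid,
                                     noise_sd = tf$noise_sd_um, seed = seed)
    p_u <- file.path(out_dir, "displacement.csv")
    p_t0 <- file.path(out_dir, "traction_truth.csv")
    p_m <- file.path(out_dir, "cell_contour.csv")
    write_displacement_csv(scene$displacement, p_u, seed = seed)
    write_traction_csv(scene$traction, p_t0, seed = seed)
    write_mask_csv(scene$mask, p_m)
    artifacts <- list(displacement = p_u, traction_truth = p_t0,
                      contour = p_m)
    trac <- NULL
    if ("invert" %in% cfg$stages) {
      stage <- "invert"
      lam <- tf$lambda
      if (identical(lam, "auto")) {
        lam <- select_lambda_lcurve(scene$displacement, gel)$lambda
        info("stage invert: L-curve selected lambda = %.3g", lam)
      } else info("stage invert: lambda = %.3g", lam)
      trac <- constrained_inverse(scene$displacement, scene$mask, gel,
                                  reg_lambda = lam)
      p_t <- file.path(out_dir, "traction_recovered.csv")
      write_traction_csv(trac, p_t, seed = seed)
      artifacts$traction_recovered <- p_t
    }
    metrics <- NULL
    if ("metrics" %in% cfg$stages && !is.null(trac)) {
      stage <- "metrics"
      info("stage metrics: summarizing cell")
      s <- summarize_cell(trac, scene$mask)
      metrics <- data.frame(rms_Pa = s$rms_traction,
                            ncm_pNum = s$net_contractile_moment,
                            polarity = s$polarity,
                            orientation_rad = s$orientation,
                            area_um2 = s$spread_area,
                            stiffness_kPa = tf$gel_kpa)
      p_met <- file.path(out_dir, "cell_metrics.csv")
      write_csv_prov(metrics, p_met, seed = seed, config_hash = hash)
      artifacts$metrics <- p_met
    }
    list(artifacts = artifacts, metrics = metrics)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate tfm|mt|cohort`, `tfm invert`,
#' `mtdyn stats`, `enrich deps`, `cohort km`, and `run` (full pipeline).
#' Intended to be called from an Rscript wrapper; see
#' `system.file("scripts", "cytomech", package = "cytomech")`.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the subcommand's result.
#' @export
cytomech_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  getopt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(getopt("--seed", "1"))
  out <- getopt("--out", ".")
  if (length(args) == 0) stop("usage: cytomech <simulate|tfm|mtdyn|enrich|cohort|run> ...")
  cmd <- args[1]
  sub <- if (length(args) >= 2 && !startsWith(args[2], "--")) args[2] else ""
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- switch(paste(cmd, sub),
    "simulate tfm" = {
      run_pipeline(list(seed = seed, out_dir = out, stages = "simulate"))
    },
    "simulate mt" = {
      traces <- simulate_mt_traces(as.integer(getopt("--n", "40")),
                                   dynamicity = as.numeric(getopt("--dynamicity", "0.1")),
                                   seed = seed)
      write_traces_csv(traces, file.path(out, "mt_traces.csv"))
      traces
    },
    "simulate cohort" = {
      d <- simulate_cohort(as.integer(getopt("--n", "200")),
                           as.numeric(getopt("--hr", "1")),
                           as.numeric(getopt("--censor", "0.2")), seed = seed)
      write_csv_prov(d, file.path(out, "cohort.csv"), seed = seed)
      d
    },
    "tfm invert" = {
      u <- read_displacement_csv(getopt("--displacements"))
      gel <- gel_substrate(as.numeric(getopt("--gel-kpa", "11")) * 1e3,
                           as.numeric(getopt("--nu", "0.5")))
      if (is.data.frame(u)) {
        grid_n <- as.integer(getopt("--grid-n", "32"))
        sp <- as.numeric(getopt("--grid-spacing", "2"))
        u <- interp_displacements(u, grid_spec(sp, c(grid_n, grid_n)))
      }
      lamopt <- getopt("--lambda", "auto")
      lam <- if (identical(lamopt, "auto"))
        select_lambda_lcurve(u, gel)$lambda else as.numeric(lamopt)
      maskfile <- getopt("--mask")
      trac <- if (!is.null(maskfile))
        constrained_inverse(u, read_mask_csv(maskfile), gel, lam)
      else fttc_inverse(u, gel, lam)
      write_traction_csv(trac, file.path(out, "traction.csv"), seed = seed)
      trac
    },
    "mtdyn stats" = {
      traces <- read_traces_csv(getopt("--traces"))
      mlc <- vapply(traces, function(tr)
        suppressWarnings(max_length_change(tr)), numeric(1))
      df <- data.frame(mt_id = vapply(traces, `[[`, character(1), "mt_id"),
                       max_length_change_pct = mlc)
      write_csv_prov(df, file.path(out, "mt_stats.csv"))
      df
    },
    "enrich deps" = {
      tab <- read_csv_prov(getopt("--table"))
      pseudo <- getopt("--pseudo", "auto")
      if (!identical(pseudo, "auto")) pseudo <- as.numeric(pseudo)
      fe <- fold_enrichment(tab, pseudo)
      deps <- dep_filter(fe, as.numeric(getopt("--threshold", "2")))
      write_csv_prov(fe[fe$protein_id %in% deps, ],
                     file.path(out, "deps.csv"))
      deps
    },
    "cohort km" = {
      d <- read_csv_prov(getopt("--cohort"))
      expr_col <- getopt("--expr-col", "expression")
      d$expression <- d[[expr_col]]
      res <- cohort_survival_analysis(d)
      write_csv_prov(res$km, file.path(out, "km_curves.csv"))
      jsonlite::write_json(list(logrank_chisq = res$logrank$statistic,
                                p_value = res$logrank$p_value,
                                threshold = res$threshold),
                           file.path(out, "tests.json"), auto_unbox = TRUE,
                           digits = NA)
      res
    },
    {
      if (cmd == "run") {
        cfgfile <- getopt("--config")
        cfg <- if (!is.null(cfgfile)) read_pipeline_config(cfgfile)
        else list(seed = seed, out_dir = out)
        run_pipeline(cfg)
      } else stop("unknown command: ", paste(cmd, sub))
    })
  invisible(res)
}
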