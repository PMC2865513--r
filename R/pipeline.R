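#' Analysis configuration
#'
#' Collects every setting for the end-to-end analysis: reference
#' structures, trajectory, thresholds and mutual-information settings.
#'
#' @param references Named character vector of reference PDB paths; names
#'   are the state labels and must include `T` and `R` (further references
#'   such as `R2` extend the PCA).
#' @param trajectory Path to a multi-model PDB trajectory.
#' @param chain_map Chain to subunit map (see [default_chain_map()]).
#' @param quat_threshold Normalized-projection threshold for state
#'   assignment (default 0.5: R below -0.5, T above +0.5).
#' @param transition_cutoff_nm rotRMSD-to-R cutoff below which a full
#'   T-to-R transition is declared (default 0.3 nm).
#' @param mi_bins,mi_fractions,mi_replicates Mutual-information estimator
#'   settings (see [extrapolated_mi()]).
#' @param truncate_mi Restrict the MI analysis to frames up to the closest
#'   approach to R (default `TRUE`).
#' @param out_dir Output directory for TSV tables, or `NULL` for none.
#' @param seed Integer seed for the MI subsampling.
#' @param dt_ns Trajectory frame spacing in ns.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(references, trajectory,
                            chain_map = default_chain_map(),
                            quat_threshold = 0.5,
                            transition_cutoff_nm = 0.3,
                            mi_bins = "auto",
                            mi_fractions = c(1, 0.5, 0.25, 0.125),
                            mi_replicates = 10,
                            truncate_mi = TRUE,
                            out_dir = NULL, seed = 1, dt_ns = 1) {
  stopifnot(is.character(references), !is.null(names(references)))
  if (!all(c("T", "R") %in% names(references))) {
    stop("references must include entries named 'T' and 'R'")
  }
  if (quat_threshold <= 0 || transition_cutoff_nm <= 0) {
    stop("thresholds must be positive")
  }
  structure(list(references = references, trajectory = trajectory,
                 chain_map = chain_map, quat_threshold = quat_threshold,
                 transition_cutoff_nm = transition_cutoff_nm,
                 mi_bins = mi_bins, mi_fractions = mi_fractions,
                 mi_replicates = mi_replicates, truncate_mi = truncate_mi,
                 out_dir = out_dir, seed = seed, dt_ns = dt_ns),
            class = "analysis_config")
}

#' Read a flat key=value configuration file
#'
#' Keys: `ref_T`, `ref_R` (required), `ref_R2` etc., `traj`, and any
#' argument of [analysis_config()] (`quat_threshold`,
#' `transition_cutoff_nm`, `mi_bins`, `mi_replicates`, `truncate_mi`,
#' `out_dir`, `seed`, `dt_ns`). Lines starting with `#` are ignored.
#'
#' @param path Path to the configuration file.
#' @return An [analysis_config()], with the source path and its MD5 hash
#'   attached for provenance.
#' @export
read_analysis_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  names(vals) <- keys

  refs <- vals[startsWith(keys, "ref_")]
  names(refs) <- sub("^ref_", "", names(refs))
  if (length(refs) == 0) stop("config defines no ref_* entries")
  num <- function(key, default) {
    if (key %in% keys) as.numeric(vals[[key]]) else default
  }
  cfg <- analysis_config(
    references = refs,
    trajectory = vals[["traj"]],
    quat_threshold = num("quat_threshold", 0.5),
    transition_cutoff_nm = num("transition_cutoff_nm", 0.3),
    mi_bins = if ("mi_bins" %in% keys) as.integer(vals[["mi_bins"]]) else "auto",
    mi_replicates = num("mi_replicates", 10),
    truncate_mi = !("truncate_mi" %in% keys && vals[["truncate_mi"]] == "false"),
    out_dir = if ("out_dir" %in% keys) vals[["out_dir"]] else NULL,
    seed = num("seed", 1),
    dt_ns = num("dt_ns", 1)
  )
  attr(cfg, "source") <- path
  attr(cfg, "md5") <- unname(tools::md5sum(path))
  cfg
}

#' Classify a trajectory's approach to the target state
#'
#' A full transition is declared when the rotRMSD to the target reference
#' dips below `cutoff`; a partial transition when it covers at least half
#' the gap between its initial value and the cutoff (i.e. dips below
#' `(initial + cutoff) / 2`); otherwise none.
#'
#' @param rotrmsd_series A [projection_series()] of rotRMSD-to-target
#'   values (nm).
#' @param cutoff Full-transition cutoff in nm (default 0.3).
#' @return `"full"`, `"partial"` or `"none"`.
#' @export
classify_transition <- function(rotrmsd_series, cutoff = 0.3) {
  v <- rotrmsd_series$value
  if (length(v) == 0) stop("empty rotRMSD series")
  if (min(v) < cutoff) return("full")
  if (min(v) < (v[1] + cutoff) / 2) return("partial")
  "none"
}

write_tsv_with_header <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full transition analysis
#'
#' Orchestrates the complete pipeline on one trajectory: reads the
#' reference structures and trajectory; builds the crystal-structure PCA
#' and projects every frame; computes the rotRMSD to R and T and the
#' rigid-body dimer-axis rotation; builds the quaternary and per-subunit
#' tertiary difference vectors and their normalized projections; assigns
#' quaternary states and conditional tertiary populations; classifies the
#' transition; and estimates the mutual information between the quaternary
#' and tertiary coordinates (after truncating at the closest approach to R
#' when a transition occurred). All tables share the trajectory frame
#' times and the report is reproducible given the configuration and seed.
#'
#' @param config An [analysis_config()] or a path to a config file for
#'   [read_analysis_config()].
#' @return Object of class `analysis_report` with elements
#'   `pca_projections`, `rotrmsd_R`, `rotrmsd_T`, `axis_rotation`,
#'   `projections` (quaternary + per-subunit normalized), `states`,
#'   `populations`, `transition`, `mi` and `config`. When
#'   `config$out_dir` is set, each table is also written as TSV with a
#'   `#`-prefixed provenance header.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  refs <- stage("read_references", lapply(config$references, read_pdb,
                                          model_index = 1,
                                          chain_map = config$chain_map))
  frames <- stage("read_trajectory", {
    fr <- read_pdb(config$trajectory, model_index = "all",
                   chain_map = config$chain_map, dt_ns = config$dt_ns)
    if (inherits(fr, "tetramer_model")) list(fr) else fr
  })

  pca_labels <- intersect(c("T", "R", "R2"), names(refs))
  basis <- stage("pca", build_xray_pca(refs[pca_labels], labels = pca_labels))
  pca_proj <- stage("pca_projection", project_frames(frames, basis))

  rr_R <- stage("rotrmsd", rot_rmsd_series(frames, refs$R))
  rr_T <- stage("rotrmsd", rot_rmsd_series(frames, refs$T))
  transition <- classify_transition(rr_R, config$transition_cutoff_nm)

  axis_rot <- stage("rigidbody", rotation_timeseries(frames, refs$T))

  dv_quat <- stage("difference_vectors",
                   build_difference_vector(refs$T, refs$R, "quaternary"))
  dv_tert <- stage("difference_vectors", {
    out <- lapply(SUBUNITS, function(su) {
      build_difference_vector(refs$T, refs$R, "tertiary", subunit = su)
    })
    names(out) <- SUBUNITS
    out
  })
  proj <- stage("projection", {
    p <- c(list(quaternary = normalized_projection(frames, dv_quat)),
           lapply(dv_tert, function(dv) normalized_projection(frames, dv)))
    names(p) <- c("quaternary", SUBUNITS)
    p
  })

  states <- stage("states", assign_quaternary_state(proj$quaternary))
  populations <- stage("populations",
                       tertiary_population(proj[SUBUNITS], states))

  mi <- stage("mutual_information", {
    coords <- proj
    if (config$truncate_mi && transition != "none") {
      coords <- lapply(coords, truncate_at_closest_approach, rotrmsd_series = rr_R)
    }
    n_mi <- nrow(coords$quaternary)
    nb <- resolve_bins(config$mi_bins, n_mi)
    if (round(n_mi * min(config$mi_fractions)) < 10 * nb) {
      NULL  # too few frames for a stable estimate: flagged, not an error
    } else {
      pairs <- lapply(SUBUNITS, function(su) c("quaternary", su))
      mi_matrix(coords, pairs = pairs, bins = config$mi_bins,
                fractions = config$mi_fractions,
                replicates = config$mi_replicates, seed = config$seed)
    }
  })

  report <- structure(list(
    pca_projections = pca_proj, rotrmsd_R = rr_R, rotrmsd_T = rr_T,
    axis_rotation = axis_rot, projections = proj, states = states,
    populations = populations, transition = transition, mi = mi,
    basis = basis, config = config
  ), class = "analysis_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Transition analysis:", nrow(x$rotrmsd_R), "frames\n")
  cat("  transition to R:", x$transition,
      sprintf("(min rotRMSD %.3f nm)", min(x$rotrmsd_R$value)), "\n")
  if (!is.null(x$mi)) {
    cat("  MI(quaternary, subunit) [nats]:\n")
    for (su in SUBUNITS) {
      cat(sprintf("    %-7s %.4f\n", su, x$mi["quaternary", su]))
    }
  }
  invisible(x)
}

#' Write report tables as TSV files
#'
#' Each table carries `#`-prefixed header lines recording the seed and,
#' when the configuration came from a file, its MD5 hash.
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  meta <- c(paste0("seed = ", cfg$seed),
            paste0("config_md5 = ", attr(cfg, "md5") %||% "NA"),
            paste0("transition = ", report$transition))
  series_tab <- data.frame(
    time_ns = report$rotrmsd_R$time,
    pc1_nm = report$pca_projections$pc1$value,
    pc2_nm = if (length(report$pca_projections) > 1) {
      report$pca_projections$pc2$value
    } else NA_real_,
    rotrmsd_R_nm = report$rotrmsd_R$value,
    rotrmsd_T_nm = report$rotrmsd_T$value,
    axis_angle_deg = report$axis_rotation$value,
    quaternary = report$projections$quaternary$value,
    alpha1 = report$projections$alpha1$value,
    beta1 = report$projections$beta1$value,
    alpha2 = report$projections$alpha2$value,
    beta2 = report$projections$beta2$value,
    state = report$states$state
  )
  write_tsv_with_header(series_tab, file.path(out_dir, "series.tsv"), meta)
  write_tsv_with_header(report$populations,
                        file.path(out_dir, "populations.tsv"), meta)
  if (!is.null(report$mi)) {
    mi_tab <- data.frame(coord_x = rep(rownames(report$mi),
                                       ncol(report$mi)),
                         coord_y = rep(colnames(report$mi),
                                       each = nrow(report$mi)),
                         mi_nats = as.vector(report$mi))
    mi_tab <- mi_tab[!is.na(mi_tab$mi_nats), ]
    write_tsv_with_header(mi_tab, file.path(out_dir, "mi.tsv"), meta)
  }
  invisible(out_dir)
}
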