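#' Load model or synthetic-generator parameters from a YAML config
#'
#' The YAML keys mirror the argument names of [spindle_params()] /
#' [synth_params()].  Missing keys take the documented defaults; an empty
#' file yields all defaults; unknown keys and invariant violations abort
#' with the offending field named.
#'
#' @param path Path to a YAML file.
#' @param type `"model"` or `"synth"`.
#' @return A `spindle_params` or `synth_params` object.
#' @export
load_config <- function(path, type = c("model", "synth")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) abort("config must be a YAML mapping")
  if (type == "model") do.call(spindle_params, cfg)
  else do.call(synth_params, cfg)
}

#' Save parameters to a YAML config
#'
#' @param params A `spindle_params` or `synth_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  x <- unclass(params)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

traj_required_cols <- c("t", "pole1", "pole2", "cenA", "cenB")

#' Read a trajectory CSV
#'
#' One CSV dialect (UTF-8, header, '.' decimal separator) is shared by the
#' simulator output and the analyser input, so in-silico and in-vivo-style
#' data flow through the same code path.  Tracked tables need columns `t`,
#' `pole1`, `pole2`, `cenA`, `cenB` (optionally `burst`, `anaphase`);
#' simulator state tables are recognised by their `x_spbL` column and
#' returned as-is.
#'
#' @param path CSV path.
#' @return A `kt_trajectory` tibble (with the `"anaphase_onset"` attribute
#'   set from the `anaphase` column when present), or a plain tibble for the
#'   simulator state dialect.
#' @export
read_trajectory <- function(path) {
  # base strtod parsing is correctly rounded, guaranteeing exact round-trips
  d <- as_tibble(utils::read.csv(path))
  d <- dplyr::mutate(d, dplyr::across(dplyr::where(is.integer), as.double))
  if ("x_spbL" %in% names(d)) {
    if (any(diff(d$t) <= 0)) abort("column `t` must be strictly increasing")
    return(d)
  }
  miss <- setdiff(traj_required_cols, names(d))
  if (length(miss) > 0) {
    abort(paste0("trajectory file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(diff(d$t) <= 0)) abort("column `t` must be strictly increasing")
  if ("anaphase" %in% names(d) && any(d$anaphase)) {
    attr(d, "anaphase_onset") <- d$t[which(d$anaphase)[1]]
  }
  class(d) <- c("kt_trajectory", class(d))
  d
}

#' Write a trajectory CSV
#'
#' Writes either a tracked table or a full simulator trajectory (the
#' per-sister/per-site state table of [sim_states()]) in the shared CSV
#' dialect at full floating-point precision, so write/read round-trips are
#' lossless.
#'
#' @param traj A `kt_trajectory` tibble or `sim_trajectory` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  d <- if (inherits(traj, "sim_trajectory")) sim_states(traj) else traj
  # 17 significant digits guarantee exact double round-trips
  d <- as.data.frame(d)
  for (nm in names(d)) {
    if (is.double(d[[nm]])) d[[nm]] <- sprintf("%.17g", d[[nm]])
  }
  readr::write_csv(d, path, progress = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a batch of runs bit-for-bit: the
#' parameter snapshot, the seeds, the package version, and an MD5 checksum
#' per output file.
#'
#' @param dir Run directory.
#' @param params Parameter object used for the runs.
#' @param seeds Integer vector of seeds.
#' @param files Files to checksum, relative to `dir`; defaults to every file
#'   in `dir` except the manifest itself.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, params, seeds, files = NULL) {
  files <- files %||% setdiff(list.files(dir), "manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    package = "spindlesim",
    version = as.character(utils::packageVersion("spindlesim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = as.integer(seeds),
    params = unclass(params)[!vapply(unclass(params), is.null, logical(1))],
    files = lapply(seq_along(files), function(i) {
      list(name = files[i], md5 = unname(sums[i]))
    }))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Verify a run manifest
#'
#' @param dir Run directory containing `manifest.json`.
#' @return A tibble with `name`, `ok` (checksum matches) per listed file.
#' @export
verify_run_manifest <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"))
  purrr::map_dfr(m$files, function(f) {
    p <- file.path(dir, f$name)
    tibble(name = f$name,
           ok = file.exists(p) && unname(tools::md5sum(p)) == f$md5)
  })
}
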