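# YAML round-trip for generator configurations.

# scalar/vector fields that serialize directly; structured fields
# (design/geometry/isotope/calibration) stay at package defaults unless the
# YAML overrides the corresponding simple knobs.
.cfg_simple_fields <- c("season_length", "cadence", "fert_days", "split",
                        "volume_l", "amplitude", "lambda", "soil_tn_pct",
                        "soil_dry_mass_g", "otu_depth")

#' Read a generator configuration from YAML
#'
#' Parses a flat-key YAML file of generator knobs and returns a full
#' [generator_config()]. Any key absent from the file keeps its package
#' default; unknown keys are an error so typos do not silently vanish.
#' Named vectors (`volume_l`, `amplitude`, `soil_tn_pct`, `soil_dry_mass_g`)
#' and the `sigma` noise map are written and read as YAML mappings.
#'
#' @param path YAML file path.
#' @return a `generator_config` object.
#' @seealso [write_generator_config()]
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(.cfg_simple_fields, "sigma")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  args <- lapply(raw[intersect(names(raw), .cfg_simple_fields)], unlist)
  if (!is.null(raw$sigma)) {
    sigma <- formals(generator_config)$sigma
    sigma <- eval(sigma)
    bad <- setdiff(names(raw$sigma), names(sigma))
    if (length(bad) > 0) {
      stop(sprintf("unknown sigma keys: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    sigma[names(raw$sigma)] <- raw$sigma
    args$sigma <- sigma
  }
  do.call(generator_config, args)
}

#' Write a generator configuration to YAML
#'
#' Serializes the simple knobs of a [generator_config()] (season layout,
#' volumes, pulse shape, noise scales, soil constants, sequencing depth) to a
#' flat-key YAML file that [read_generator_config()] restores exactly. The
#' structured members (design, geometry, isotope constants, calibration) are
#' not serialized; they are reconstructed from package defaults on read.
#'
#' @param config a `generator_config` object.
#' @param path output YAML file path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  out <- lapply(config[.cfg_simple_fields], function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  out$sigma <- config$sigma
  yaml::write_yaml(out, path)
  invisible(path)
}
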