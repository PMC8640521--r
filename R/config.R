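#' Write an experiment configuration to YAML
#'
#' Serialises an `experiment_config` into a single plain-text file:
#' experiment id, seed, protocol parameters, dynamics and connectivity
#' overrides, and MEG read-out settings.  Anatomy is stored structurally
#' (fields and edges) so that edited configs can rewire the model.
#'
#' @param config an `experiment_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @seealso [read_experiment_config()]
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- list(
    experiment = config$experiment,
    seed = config$seed,
    smoke = config$smoke,
    protocol = config$protocol,
    dynamics = unclass(config$dynamics),
    connectivity = lapply(unclass(config$connectivity), function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    meg = list(class_weights = as.list(config$meg$class_weights),
               include_thalamic_targets =
                 config$meg$include_thalamic_targets),
    anatomy = list(
      fields = lapply(seq_len(nrow(config$anatomy$fields)), function(i)
        as.list(config$anatomy$fields[i, ])),
      edges = lapply(seq_len(nrow(config$anatomy$edges)), function(i)
        as.list(config$anatomy$edges[i, ])))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' Reconstructs an `experiment_config` written by
#' [write_experiment_config()].  Any omitted section falls back to the
#' experiment's defaults, so minimal configs need only `experiment` (and
#' typically `seed`).
#'
#' @param path YAML path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$experiment)) stop("config must name an experiment (1-5)")
  anatomy <- if (!is.null(cfg$anatomy)) {
    fields <- do.call(rbind, lapply(cfg$anatomy$fields, function(f)
      data.frame(name = f$name, level = f$level,
                 n_columns = if (is.null(f$n_columns)) 16L else f$n_columns,
                 stringsAsFactors = FALSE)))
    edges <- do.call(rbind, lapply(cfg$anatomy$edges, function(e)
      data.frame(from = e$from, to = e$to, class = e$class,
                 stringsAsFactors = FALSE)))
    new_anatomy(fields, edges)
  } else default_anatomy()
  connectivity <- if (!is.null(cfg$connectivity)) {
    cc <- cfg$connectivity
    connectivity_params(
      gain_ff = unlist(cc$gain_ff), fb_ratio = cc$fb_ratio,
      sigma = unlist(cc$sigma), w_self = cc$w_self, lat_exc = cc$lat_exc,
      gain_ie = cc$gain_ie, sigma_ie = cc$sigma_ie, ie_span = cc$ie_span,
      w_ei = cc$w_ei)
  } else connectivity_params()
  dynamics <- if (!is.null(cfg$dynamics)) {
    dd <- cfg$dynamics
    dynamics_params(tau_m = dd$tau_m, theta = dd$theta,
                    tau_o_cortex = dd$tau_o_cortex,
                    tau_o_thalamus = dd$tau_o_thalamus,
                    tau_rec = dd$tau_rec, dt = dd$dt,
                    depress_inhibitory = dd$depress_inhibitory,
                    depress_ie = dd$depress_ie, stsd = dd$stsd)
  } else NULL
  meg <- if (!is.null(cfg$meg)) {
    meg_params(class_weights = unlist(cfg$meg$class_weights),
               include_thalamic_targets =
                 isTRUE(cfg$meg$include_thalamic_targets))
  } else meg_params()
  experiment_config(cfg$experiment,
                    seed = if (is.null(cfg$seed)) 1 else cfg$seed,
                    smoke = isTRUE(cfg$smoke),
                    anatomy = anatomy, connectivity = connectivity,
                    dynamics = dynamics, meg = meg,
                    protocol = if (is.null(cfg$protocol)) list()
                               else cfg$protocol)
}
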