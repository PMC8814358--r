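#' Model configuration
#'
#' Builds an [MLG1Config-class] with the model's standard parameter values.
#' Thresholds and coefficients follow the published parameterisation of the
#' detector; the remaining values (persistence steepness `mu`, spike-buffer
#' length `N_t`, the winner-take-all window, the rotation-veto vote and the
#' warm-up length) default to the values documented below and are all
#' overridable.
#'
#' @param N_p luminance persistence of the photoreceptor layer, in frames.
#' @param mu steepness of the logistic persistence coefficients
#'   `a_i = 1/(1 + exp(mu * i))`; larger values make older frames fade faster.
#' @param W_I weight of the lateral inhibition pathway.
#' @param inhibition_sign -1 for subtractive lateral inhibition (default),
#'   +1 to add the delayed surround instead.
#' @param C_w gain constant of the grouping-layer normaliser.
#' @param Delta_c small positive floor shared by the grouping normaliser and
#'   the adaptation coefficient.
#' @param T_g grouping threshold: grouped excitations whose magnitude falls
#'   below `T_g` are zeroed (gray-level units).
#' @param c_i1 adaptation increment while excitation rises and accelerates.
#' @param c_i2 adaptation increment while excitation rises but decelerates.
#' @param c_a adaptation decrement while excitation falls.
#' @param tau inter-frame time constant in seconds; defaults to `1/fps`.
#' @param fps frame rate used to derive `tau` when `tau` is not given.
#' @param T_s spike threshold on the sigmoidal activation (in (0.5, 1)).
#' @param n_sp spikes required within the alarm window to raise an alarm.
#' @param N_t length of the spike buffer inspected by the alarm rule;
#'   defaults to `n_sp + 1`.
#' @param N_a persistence window of the feed-forward inhibition, in frames.
#' @param T_F0 base value of the adaptive FFI threshold.
#' @param a_ffi persistence of the adaptive FFI threshold, in (0, 1).
#' @param wta_window alarm-history window scored by the winner-take-all layer.
#' @param rotation_veto_count sectors whose FFI must be active to veto the
#'   whole ensemble as self-rotation.
#' @param warmup_frames initial frames with spikes and alarms suppressed.
#' @param sfa_enabled logical; `FALSE` freezes the adaptation coefficient at
#'   `sfa_fixed_c` (used to probe what adaptation contributes).
#' @param sfa_fixed_c constant gain used when adaptation is disabled.
#' @return an [MLG1Config-class] object.
#' @examples
#' cfg <- mlg1Config()
#' cfg@T_s
#' urbanConfig()@n_sp  # stricter alarm rule for cluttered scenes
#' @export
mlg1Config <- function(N_p = 1L, mu = 1.0, W_I = 0.3, inhibition_sign = -1,
                       C_w = 4, Delta_c = 0.01, T_g = 30, c_i1 = 0.5,
                       c_i2 = 0.3, c_a = 0.3, tau = 1 / fps, fps = 30,
                       T_s = 0.7, n_sp = 4L, N_t = n_sp + 1L, N_a = 1L,
                       T_F0 = 15, a_ffi = 0.02, wta_window = 8L,
                       rotation_veto_count = 10L, warmup_frames = 3L,
                       sfa_enabled = TRUE, sfa_fixed_c = 1.0) {
  new("MLG1Config",
      N_p = as.integer(N_p), mu = mu, W_I = W_I,
      inhibition_sign = inhibition_sign, C_w = C_w, Delta_c = Delta_c,
      T_g = T_g, c_i1 = c_i1, c_i2 = c_i2, c_a = c_a, tau = tau, T_s = T_s,
      n_sp = as.integer(n_sp), N_t = as.integer(N_t), N_a = as.integer(N_a),
      T_F0 = T_F0, a_ffi = a_ffi, wta_window = as.integer(wta_window),
      rotation_veto_count = as.integer(rotation_veto_count),
      warmup_frames = as.integer(warmup_frames), sfa_enabled = sfa_enabled,
      sfa_fixed_c = sfa_fixed_c)
}

#' Configuration profile for cluttered urban scenes
#'
#' The standard configuration with a stricter spike threshold (`T_s = 0.88`)
#' and a longer spike requirement (`n_sp = 6`), suited to dynamic cluttered
#' backgrounds.
#'
#' @param ... further overrides forwarded to [mlg1Config()].
#' @return an [MLG1Config-class] object.
#' @export
urbanConfig <- function(...) {
  mlg1Config(T_s = 0.88, n_sp = 6L, ...)
}

#' Convert a configuration to/from a plain list
#'
#' @param config an [MLG1Config-class].
#' @return `configAsList()`: a named list of scalar parameters.
#' @export
configAsList <- function(config) {
  stopifnot(is(config, "MLG1Config"))
  nm <- slotNames("MLG1Config")
  out <- lapply(nm, function(s) slot(config, s))
  names(out) <- nm
  out
}

#' @rdname configAsList
#' @param values named list, e.g. as produced by [configAsList()] or read
#'   from a YAML file; unknown names are an error.
#' @return `configFromList()`: an [MLG1Config-class].
#' @export
configFromList <- function(values) {
  known <- slotNames("MLG1Config")
  unknown <- setdiff(names(values), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  args <- values
  # keep N_t's default tied to n_sp unless given explicitly
  do.call(mlg1Config, args)
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML whose keys are the parameter symbols
#' (`W_I`, `C_w`, `T_g`, ...). `readConfig()` accepts a `profile` key naming
#' a preset (`"default"` or `"urban"`) that the remaining keys then override.
#'
#' @param path file path.
#' @return `readConfig()`: an [MLG1Config-class].
#' @export
readConfig <- function(path) {
  values <- yaml::read_yaml(path)
  profile <- values$profile
  values$profile <- NULL
  if (!is.null(profile) && identical(profile, "urban")) {
    base <- configAsList(urbanConfig())
  } else {
    base <- configAsList(mlg1Config())
  }
  base[names(values)] <- values
  configFromList(base)
}

#' @rdname readConfig
#' @param config an [MLG1Config-class] to serialise.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(configAsList(config), path, precision = 15L)
  invisible(path)
}

#' @describeIn mlg1Config compact display of a configuration.
#' @param object an [MLG1Config-class].
#' @export
setMethod("show", "MLG1Config", function(object) {
  vals <- configAsList(object)
  cat("MLG1Config\n")
  cat(" ", paste0(names(vals), "=", unlist(lapply(vals, format)),
                  collapse = " "), "\n")
})
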