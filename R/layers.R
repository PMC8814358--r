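# The per-sector partial neural network, layer by layer. Each function is a
# pure operation on the state the caller holds; runMLG1s() wires them into
# the frame loop. All arithmetic is double precision and deterministic.

#' Logistic persistence coefficient
#'
#' Weight of the luminance change seen `i` frames ago on the current
#' photoreceptor output: `a_i = 1 / (1 + exp(mu * i))`. Strictly decreasing
#' in `i` for positive `mu`, so older changes fade. Vectorised over `i`.
#'
#' @param mu steepness parameter.
#' @param i frame lag, `i >= 1`.
#' @return numeric in (0, 1).
#' @examples
#' persistenceCoefficient(1, 1)  # 1/(1 + e) ~= 0.2689
#' @export
persistenceCoefficient <- function(mu, i) {
  if (any(i < 1)) stop("frame lag i must be >= 1")
  1 / (1 + exp(mu * i))
}

#' Photoreceptor layer: persistent luminance change
#'
#' Per-pixel luminance change with a fading memory of earlier changes:
#' `P(t) = sum_i a_i P(t - i) + L(t) - L(t - 1)` over the persistence window.
#' On the very first frame there is no previous luminance and the output is
#' zero everywhere (warm-up rule, applied by the caller that owns the
#' history).
#'
#' @param L_t current luminance frame (matrix, gray levels 0..255).
#' @param L_prev previous luminance frame.
#' @param P_history list of earlier outputs, most recent first (up to `N_p`
#'   are used; shorter or empty during warm-up).
#' @param config an [MLG1Config-class] (uses `mu`, `N_p`).
#' @return signed numeric matrix.
#' @export
photoreceptorUpdate <- function(L_t, L_prev, P_history, config) {
  if (!all(dim(L_t) == dim(L_prev))) stop("frame dimension mismatch")
  P <- L_t - L_prev
  nUse <- min(length(P_history), config@N_p)
  if (nUse > 0) {
    a <- persistenceCoefficient(config@mu, seq_len(nUse))
    for (i in seq_len(nUse)) {
      P <- P + a[i] * P_history[[i]]
    }
  }
  P
}

#' Excitation and lateral inhibition pathways
#'
#' The excitation cell copies the photoreceptor output; the inhibition cell
#' is the one-frame-delayed photoreceptor output spread to each cell's
#' neighbours through the 3x3 surround kernel ([inhibitionKernel()]), with
#' zero padding at the borders.
#'
#' @param P_t current photoreceptor output (matrix).
#' @param P_prev previous photoreceptor output.
#' @return list with signed matrices `E` and `I`.
#' @export
lateralPathways <- function(P_t, P_prev) {
  if (!all(dim(P_t) == dim(P_prev))) stop("frame dimension mismatch")
  list(E = P_t, I = conv3x3(P_prev, inhibitionKernel()))
}

#' Summation layer
#'
#' Combines excitation and inhibition: `S = E + inhibition_sign * W_I * I`.
#' The default sign (-1) realises subtractive lateral inhibition; +1 adds
#' the delayed surround instead.
#'
#' @param E,I matrices from [lateralPathways()].
#' @param config an [MLG1Config-class] (uses `W_I`, `inhibition_sign`).
#' @return signed numeric matrix.
#' @export
summationLayer <- function(E, I, config) {
  if (!all(dim(E) == dim(I))) stop("frame dimension mismatch")
  E + config@inhibition_sign * config@W_I * I
}

#' Grouping layer
#'
#' Enhances clustered (expanding-edge) excitation and suppresses isolated
#' noise. The passing coefficient `Ce` is the 3x3 equal-weighted average of
#' `S`; the frame-wide normaliser is `omega = Delta_c + max|Ce| / C_w`; the
#' grouped excitation is `Gtilde = S * Ce / omega`, and values whose
#' magnitude falls below `T_g` are zeroed to give `G`. An all-zero input
#' yields `omega = Delta_c` and a zero output (no division hazard).
#'
#' @param S summation-layer output (matrix, at least 3x3).
#' @param config an [MLG1Config-class] (uses `Delta_c`, `C_w`, `T_g`).
#' @return list with `Gtilde`, thresholded `G`, and the scalar `omega`.
#' @export
groupingLayer <- function(S, config) {
  if (nrow(S) < 3L || ncol(S) < 3L) stop("grouping needs at least a 3x3 frame")
  Ce <- conv3x3(S, groupingKernel())
  omega <- config@Delta_c + max(abs(Ce)) / config@C_w
  Gtilde <- S * Ce / omega
  G <- Gtilde
  G[abs(G) < config@T_g] <- 0
  list(Gtilde = Gtilde, G = G, omega = omega)
}

#' Membrane potential of one sector
#'
#' Rectified sum of the thresholded grouping output over the sector's mask:
#' `m = sum |G|` over masked pixels.
#'
#' @param G thresholded grouping output (matrix).
#' @param mask logical matrix of the same shape, or an integer index vector
#'   (as stored in `SectorGeometry@maskIndex`).
#' @return non-negative scalar.
#' @export
membranePotential <- function(G, mask) {
  if (is.logical(mask)) {
    if (!all(dim(G) == dim(mask))) stop("mask dimension mismatch")
    sum(abs(G[mask]))
  } else {
    sum(abs(G[mask]))
  }
}

#' Sigmoidal activation of an MLG1-like unit
#'
#' Maps the membrane potential to `M = 1 / (1 + exp(-c * m / nCell))`, the
#' normalised activation in `[0.5, 1)` for non-negative `m` (0.5 exactly at
#' rest).
#'
#' @param m membrane potential, `m >= 0`.
#' @param c adaptation coefficient, `c > 0`.
#' @param nCell number of cells (pixels) in the sector's receptive field.
#' @return activation in `[0.5, 1)`.
#' @examples
#' activationLevel(0, 1, 100)  # exactly 0.5 at rest
#' @export
activationLevel <- function(m, c, nCell) {
  if (any(nCell <= 0)) stop("configuration error: nCell must be positive")
  1 / (1 + exp(-c * m / nCell))
}

#' Discrete first and second derivatives of the membrane potential
#'
#' Finite differences over consecutive frames: `m' = (m_t - m_t1) / tau` and
#' `m'' = (m_t - 2 m_t1 + m_t2) / tau^2`. During warm-up (when fewer than
#' three values exist, signalled by passing `NA` for a missing value) both
#' derivatives are zero.
#'
#' @param m_t,m_t1,m_t2 membrane potentials at the current and two previous
#'   frames (`NA` while the history is unfilled).
#' @param tau inter-frame time constant in seconds.
#' @return list with scalars `d1` and `d2`.
#' @export
discreteDerivatives <- function(m_t, m_t1, m_t2, tau) {
  if (tau <= 0) stop("tau must be positive")
  if (anyNA(c(m_t, m_t1, m_t2))) return(list(d1 = 0, d2 = 0))
  list(d1 = (m_t - m_t1) / tau,
       d2 = (m_t - 2 * m_t1 + m_t2) / tau^2)
}

#' Spike-frequency adaptation update
#'
#' The adaptation coefficient grows while excitation rises (`+ c_i1` when
#' also accelerating, `+ c_i2` when decelerating) and collapses while it
#' falls (`- c_a`); a candidate at or below zero is floored to `Delta_c`.
#' This sharpens looming selectivity: sustained growth of excitation drives
#' the gain up, a receding stimulus drives it to the floor. The initial value
#' is `Delta_c`. When adaptation is disabled in the configuration the
#' coefficient is held at `sfa_fixed_c`.
#'
#' @param c_prev previous coefficient (`>= Delta_c`).
#' @param d1,d2 first and second discrete derivatives of the membrane
#'   potential.
#' @param config an [MLG1Config-class].
#' @return updated coefficient, `>= Delta_c` (or `sfa_fixed_c` when
#'   adaptation is disabled).
#' @export
sfaUpdate <- function(c_prev, d1, d2, config) {
  if (!config@sfa_enabled) return(config@sfa_fixed_c)
  cand <- if (d1 > 0 && d2 >= 0) {
    c_prev + config@c_i1
  } else if (d1 > 0) {
    c_prev + config@c_i2
  } else {
    c_prev - config@c_a
  }
  if (cand <= 0) config@Delta_c else cand
}

#' Feed-forward inhibition of one sector
#'
#' Mean absolute luminance change over the sector's receptive field on the
#' previous frame, with a fading memory of earlier FFI values:
#' `F(t) = sum_j a_j F(t - j) + mean |P(t - 1)|` over the mask, with the
#' persistence coefficients from [persistenceCoefficient()].
#'
#' @param P_prev previous photoreceptor output (matrix).
#' @param maskIndex integer index vector of the sector's pixels.
#' @param nCell number of pixels in the sector.
#' @param F_history numeric vector of earlier FFI values, most recent first
#'   (up to `N_a` are used).
#' @param config an [MLG1Config-class] (uses `mu`, `N_a`).
#' @return non-negative scalar.
#' @export
ffiUpdate <- function(P_prev, maskIndex, nCell, F_history, config) {
  F_val <- sum(abs(P_prev[maskIndex])) / nCell
  nUse <- min(length(F_history), config@N_a)
  if (nUse > 0) {
    a <- persistenceCoefficient(config@mu, seq_len(nUse))
    F_val <- F_val + sum(a[seq_len(nUse)] * F_history[seq_len(nUse)])
  }
  F_val
}

#' Adaptive feed-forward inhibition threshold
#'
#' `T_FFI(t) = T_F0 + a_ffi * T_FFI(t - 1)`, initialised at `T_F0`; the
#' recursion converges monotonically to `T_F0 / (1 - a_ffi)`.
#'
#' @param T_prev previous threshold value.
#' @param config an [MLG1Config-class] (uses `T_F0`, `a_ffi`).
#' @return updated threshold.
#' @export
ffiThreshold <- function(T_prev, config) {
  if (T_prev <= 0) stop("T_prev must be positive")
  config@T_F0 + config@a_ffi * T_prev
}

#' Spike decision
#'
#' A sector spikes when its activation reaches the spike threshold and its
#' feed-forward inhibition stays below the adaptive threshold:
#' `spike = 1` iff `M >= T_s` and `F < T_FFI`.
#'
#' @param M activation.
#' @param F feed-forward inhibition value.
#' @param T_FFI current FFI threshold.
#' @param config an [MLG1Config-class] (uses `T_s`).
#' @return integer 0/1.
#' @export
spikeDecision <- function(M, F, T_FFI, config) {
  if (!all(is.finite(c(M, F, T_FFI)))) stop("non-finite spike inputs")
  as.integer(M >= config@T_s && F < T_FFI)
}

#' Collision alarm
#'
#' A collision alarm is raised when at least `n_sp` spikes occurred within
#' the last `N_t` frames.
#'
#' @param spikeBuffer integer 0/1 vector of the last `N_t` spike bits.
#' @param config an [MLG1Config-class] (uses `n_sp`, `N_t`).
#' @return integer 0/1.
#' @export
collisionAlarm <- function(spikeBuffer, config) {
  if (length(spikeBuffer) != config@N_t) {
    stop("spike buffer must hold exactly N_t bits")
  }
  as.integer(sum(spikeBuffer) >= config@n_sp)
}
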