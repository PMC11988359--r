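## Gyromagnetic ratio of 1H, rad s^-1 T^-1.
GAMMA_1H <- 2.6751525e8

#' Define a diffusion-encoding sequence
#'
#' Constructs the description of one diffusion acquisition: either a pulsed
#' gradient spin echo (`pgse`, two rectangular lobes) or a cosine-modulated
#' oscillating gradient spin echo (`ogse_cos`, two cosine lobes with an
#' integer number of full periods each). User-facing units are milliseconds
#' for times, Hz for the oscillation frequency and s/mm^2 for b-values;
#' conversions to SI happen internally.
#'
#' @param kind `"pgse"` or `"ogse_cos"`.
#' @param label unique sequence label, e.g. `"ogse25"`.
#' @param b_values diffusion weightings, s/mm^2; the first entry must be 0.
#' @param nsa number of signal averages per b-value (same length as
#'   `b_values`).
#' @param delta gradient lobe duration \eqn{\delta}, ms.
#' @param Delta lobe separation \eqn{\Delta} (leading edge to leading edge),
#'   ms.
#' @param te echo time, ms; must contain both lobes.
#' @param f oscillation frequency, Hz (`ogse_cos` only; must equal
#'   `n_cycles / delta` with `delta` in seconds).
#' @param n_cycles full cosine periods per lobe (`ogse_cos` only).
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(kind = c("pgse", "ogse_cos"), label, b_values,
                          nsa = rep(1L, length(b_values)),
                          delta, Delta, te, f = 0, n_cycles = 0L) {
  kind <- match.arg(kind)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (length(nsa) != length(b_values))
    stop("`nsa` must have the same length as `b_values`")
  if (any(b_values < 0)) stop("b-values must be non-negative")
  if (b_values[1] != 0) stop("the first b-value must be 0 (reference image)")
  if (any(nsa < 1)) stop("`nsa` entries must be >= 1")
  if (delta <= 0) stop("`delta` must be positive")
  if (Delta < delta)
    stop("`Delta` (leading edge to leading edge) must be >= `delta`")
  if (te < Delta + delta)
    stop("`te` too short: second lobe ends at Delta + delta = ",
         Delta + delta, " ms > te = ", te, " ms")
  if (kind == "ogse_cos") {
    if (n_cycles < 1 || n_cycles != round(n_cycles))
      stop("`n_cycles` must be a positive integer for ogse_cos")
    f_implied <- n_cycles / (delta * 1e-3)
    if (abs(f - f_implied) > 1e-9 * f_implied)
      stop("ogse_cos requires f = n_cycles/delta exactly; got f = ", f,
           " Hz but n_cycles/delta = ", f_implied, " Hz")
  } else {
    f <- 0
    n_cycles <- 0L
  }
  structure(
    list(kind = kind, label = label, f = f, n_cycles = as.integer(n_cycles),
         delta = delta, Delta = Delta, te = te,
         b_values = as.numeric(b_values), nsa = as.numeric(nsa)),
    class = "sequence_spec")
}

#' Bundle sequences into an acquisition protocol
#'
#' @param sequences list of [sequence_spec()] objects; labels must be unique.
#'   Microstructure fitting requires at least one `pgse` and one `ogse_cos`
#'   sequence so that two distinct diffusion times are sampled.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1 (default 1H).
#' @return An object of class `dwi_protocol`.
#' @export
protocol <- function(sequences, gamma = GAMMA_1H) {
  stopifnot(is.list(sequences), length(sequences) >= 1L)
  if (!all(vapply(sequences, inherits, logical(1), "sequence_spec")))
    stop("`sequences` must be a list of sequence_spec objects")
  labels <- vapply(sequences, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("sequence labels must be unique")
  kinds <- vapply(sequences, `[[`, character(1), "kind")
  if (!("pgse" %in% kinds) || !("ogse_cos" %in% kinds))
    warning("protocol lacks a pgse/ogse_cos pair; IMPULSED fitting needs both")
  names(sequences) <- labels
  structure(list(sequences = sequences, gamma = gamma),
            class = "dwi_protocol")
}

#' Effective diffusion time of a sequence
#'
#' \eqn{\Delta - \delta/3} for PGSE; \eqn{1/(4f)} for cosine OGSE.
#'
#' @param seq a [sequence_spec()].
#' @return Effective diffusion time, ms. Independent of gradient amplitude
#'   and b-value.
#' @export
effective_diffusion_time <- function(seq) {
  stopifnot(inherits(seq, "sequence_spec"))
  switch(seq$kind,
         pgse = seq$Delta - seq$delta / 3,
         ogse_cos = 1000 / (4 * seq$f),
         stop("unknown sequence kind: ", seq$kind))
}

## b-value normalisation constant c such that b_SI = gamma^2 g^2 c,
## returned in SI (s^3). PGSE: delta^2 (Delta - delta/3).
## Cosine OGSE, integer cycles, two lobes: delta / omega^2.
b_norm_constant <- function(seq) {
  delta_s <- seq$delta * 1e-3
  if (seq$kind == "pgse") {
    delta_s^2 * (seq$Delta - seq$delta / 3) * 1e-3
  } else {
    omega <- 2 * pi * seq$f
    delta_s / omega^2
  }
}

#' Gradient amplitude needed to realise a b-value
#'
#' Inverts the closed-form b-value expressions: for PGSE
#' \eqn{b = \gamma^2 g^2 \delta^2 (\Delta - \delta/3)} and for cosine OGSE
#' with an integer number of periods per lobe (both lobes included)
#' \eqn{b = \gamma^2 g^2 \delta / \omega^2}, \eqn{\omega = 2\pi f}.
#'
#' @param seq a [sequence_spec()].
#' @param b b-value, s/mm^2.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return Gradient amplitude, T/m.
#' @export
gradient_amplitude_from_b <- function(seq, b, gamma = GAMMA_1H) {
  stopifnot(inherits(seq, "sequence_spec"), all(b >= 0))
  if (any(b > 0) && seq$delta <= 0)
    stop("cannot realise b > 0 with zero-duration gradient lobes")
  b_si <- b * 1e6                       # s/mm^2 -> s/m^2
  sqrt(b_si / (gamma^2 * b_norm_constant(seq)))
}

#' Build the effective gradient waveform of a sequence
#'
#' Samples the effective (sign-inverted after the refocusing pulse) gradient
#' waveform at bin midpoints on a uniform grid. PGSE gives two rectangular
#' lobes of opposite effective sign; cosine OGSE gives two cosine lobes with
#' `n_cycles` full periods each, the second sign-flipped. Idealised
#' rectangles/cosines: ramps are not modelled.
#'
#' @param seq a [sequence_spec()].
#' @param g gradient amplitude, T/m.
#' @param dt sampling interval, ms; must resolve an oscillation period with
#'   at least 100 samples.
#' @return A `waveform` object: `times` (bin midpoints, ms), `g_eff` (T/m),
#'   `dt` (ms).
#' @export
build_waveform <- function(seq, g, dt = 0.005) {
  stopifnot(inherits(seq, "sequence_spec"), g >= 0, dt > 0)
  if (seq$kind == "ogse_cos") {
    period_ms <- 1000 / seq$f
    if (period_ms / dt < 100)
      stop("dt = ", dt, " ms gives fewer than 100 samples per period")
  }
  n <- ceiling(seq$te / dt)
  tm <- (seq_len(n) - 0.5) * dt          # bin midpoints, ms
  g_eff <- numeric(n)
  in1 <- tm > 0 & tm < seq$delta
  in2 <- tm > seq$Delta & tm < seq$Delta + seq$delta
  if (seq$kind == "pgse") {
    g_eff[in1] <- g
    g_eff[in2] <- -g
  } else {
    omega_ms <- 2 * pi * seq$f * 1e-3    # rad/ms
    g_eff[in1] <- g * cos(omega_ms * tm[in1])
    g_eff[in2] <- -g * cos(omega_ms * (tm[in2] - seq$Delta))
  }
  structure(list(times = tm, g_eff = g_eff, dt = dt, te = seq$te),
            class = "waveform")
}

#' Recompute the b-value of a sampled waveform
#'
#' Numerical quadrature of \eqn{b = \int_0^{TE} |q(t)|^2 dt} with
#' \eqn{q(t) = \gamma \int_0^t g_{eff}(s) ds}. Serves as the
#' waveform-level cross-check of the closed-form b-value expressions used by
#' [gradient_amplitude_from_b()].
#'
#' @param wf a `waveform` from [build_waveform()].
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return b-value, s/mm^2.
#' @export
b_value_from_waveform <- function(wf, gamma = GAMMA_1H) {
  stopifnot(inherits(wf, "waveform"))
  dt_s <- wf$dt * 1e-3
  ## q at bin midpoints: full contribution of previous bins + half of own bin
  q <- gamma * (cumsum(wf$g_eff) - wf$g_eff / 2) * dt_s
  sum(q^2) * dt_s / 1e6                  # s/m^2 -> s/mm^2
}

#' The combined PGSE + OGSE breast protocol
#'
#' Builds the three-sequence 3T protocol used throughout this package:
#' cosine OGSE at 25 Hz (one cycle per lobe, effective diffusion time 10 ms,
#' b up to 1000 s/mm^2), cosine OGSE at 50 Hz (two cycles, 5 ms, b up to
#' 250 s/mm^2), and PGSE at an effective diffusion time of 78.4 ms (b up to
#' 1800 s/mm^2), with the published per-b signal averages. Loaded from the
#' JSON descriptor shipped in `inst/extdata/breast_protocol.json`.
#'
#' @return A `dwi_protocol`.
#' @export
breast_protocol <- function() {
  read_protocol(system.file("extdata", "breast_protocol.json",
                            package = "impulsed", mustWork = TRUE))
}

#' Read / write a protocol descriptor
#'
#' Protocols are serialised as JSON mirroring the [sequence_spec()] fields.
#'
#' @param path file path.
#' @return [read_protocol()] returns a `dwi_protocol`;
#'   [write_protocol()] invisibly returns `path`.
#' @export
read_protocol <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  seqs <- lapply(doc$sequences, function(s)
    sequence_spec(kind = s$kind, label = s$label,
                  b_values = unlist(s$b_values), nsa = unlist(s$nsa),
                  delta = s$delta, Delta = s$Delta, te = s$te,
                  f = if (is.null(s$f)) 0 else s$f,
                  n_cycles = if (is.null(s$n_cycles)) 0L else s$n_cycles))
  gamma <- if (is.null(doc$gamma)) GAMMA_1H else doc$gamma
  protocol(seqs, gamma = gamma)
}

#' @param prot a `dwi_protocol`.
#' @rdname read_protocol
#' @export
write_protocol <- function(prot, path) {
  stopifnot(inherits(prot, "dwi_protocol"))
  doc <- list(
    gamma = prot$gamma,
    sequences = lapply(unname(prot$sequences), function(s)
      s[c("kind", "label", "f", "n_cycles", "delta", "Delta", "te",
          "b_values", "nsa")]))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat(sprintf("<sequence_spec> %s (%s)\n", x$label, x$kind))
  if (x$kind == "ogse_cos")
    cat(sprintf("  f = %g Hz, %d cycle(s)/lobe\n", x$f, x$n_cycles))
  cat(sprintf("  delta = %g ms, Delta = %g ms, TE = %g ms, t_diff = %g ms\n",
              x$delta, x$Delta, x$te, effective_diffusion_time(x)))
  cat("  b (s/mm^2):", paste(x$b_values, collapse = ", "), "\n")
  cat("  nsa       :", paste(x$nsa, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.dwi_protocol <- function(x, ...) {
  cat(sprintf("<dwi_protocol> %d sequence(s), gamma = %g rad/s/T\n",
              length(x$sequences), x$gamma))
  for (s in x$sequences) print(s)
  invisible(x)
}
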