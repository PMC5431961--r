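#' Electrode-electrolyte interface circuit
#'
#' Equivalent circuit of an implanted metal electrode: a faradaic impedance
#' `Zf` (irreversible charge injection) in parallel with a double-layer
#' capacitance `Cdl` (capacitive charge injection), in series with the
#' solution resistance `Rs` between the two tips of the bipolar electrode.
#'
#' @param Zf Faradaic impedance (Ohm).  Default 0.1 MOhm (stainless steel).
#' @param Cdl Double-layer capacitance (F).  Default 1 mF.
#' @param Rs Solution/tissue resistance (Ohm).  Default from
#'   [tissue_resistance()] with grey-matter conductivity and the twisted-wire
#'   electrode geometry (125 um tips, 400 um apart).
#' @return An object of class `interface_circuit`.
#' @examples
#' time_constant(interface_circuit())   # 100 s
#' @export
interface_circuit <- function(Zf = 0.1e6, Cdl = 1e-3,
                              Rs = tissue_resistance()) {
  stopifnot(Zf > 0, Cdl >= 0, Rs > 0)
  structure(list(Zf = Zf, Cdl = Cdl, Rs = Rs), class = "interface_circuit")
}

#' @export
print.interface_circuit <- function(x, ...) {
  cat(sprintf(
    "Interface circuit: Zf = %.3g kOhm || Cdl = %.3g mF, Rs = %.3g kOhm (tau = %.3g s)\n",
    x$Zf / 1e3, x$Cdl * 1e3, x$Rs / 1e3, time_constant(x)))
  invisible(x)
}

#' Interface time constant
#'
#' The charge-accumulation time constant of the electrode-electrolyte
#' interface, `Zf * Cdl`.
#'
#' @param c An [interface_circuit()].
#' @return Time constant (s).
#' @export
time_constant <- function(c) {
  stopifnot(inherits(c, "interface_circuit"))
  c$Zf * c$Cdl
}

#' Tissue resistance between bipolar electrode tips
#'
#' Resistance of a uniform cylindrical conductor of the tip cross-section
#' spanning the inter-tip separation:
#' `R = separation / (sigma * pi * (tip_diameter/2)^2)`.
#'
#' @param sigma Tissue conductivity (S/m).  Default 0.35 (grey matter).
#' @param tip_diameter Electrode tip diameter (m).  Default 125 um.
#' @param separation Tip separation (m).  Default 400 um.
#' @return Resistance (Ohm).
#' @examples
#' tissue_resistance() / 1e3   # ~93 kOhm
#' @export
tissue_resistance <- function(sigma = 0.35, tip_diameter = 125e-6,
                              separation = 400e-6) {
  stopifnot(sigma > 0, tip_diameter > 0, separation > 0)
  separation / (sigma * pi * (tip_diameter / 2)^2)
}

#' Interface circuit response to a stimulation drive
#'
#' Integrates `Cdl dVdl/dt = i - Vdl/Zf`.  In current mode the tissue
#' current equals the drive (ideal current source); the double-layer voltage
#' is tracked for diagnostics.  In voltage mode the applied voltage drives
#' `i = (Vapp - Vdl)/Rs`, so charge accumulation at the interface attenuates
#' the delivered current toward `Vapp/(Rs + Zf)`.
#'
#' @param c An [interface_circuit()].
#' @param drive Numeric vector: current (uA) in current mode, voltage (V)
#'   in voltage mode, sampled at `1/dt`.
#' @param mode `"current"` or `"voltage"`.
#' @param dt Integration step (s).  In voltage mode `dt` must not exceed a
#'   tenth of the effective time constant `Cdl * Rs * Zf / (Rs + Zf)`.
#' @return A list with numeric vectors `current` (uA, the tissue current)
#'   and `v_dl` (the double-layer voltage: uV in current mode, V in voltage
#'   mode, matching the drive units).
#' @examples
#' c <- interface_circuit()
#' r <- interface_response(c, rep(1, 1000), mode = "current", dt = 0.1)
#' max(r$v_dl) * 1e-6   # double-layer volts after 100 s at 1 uA
#' @export
interface_response <- function(c, drive, mode = c("current", "voltage"), dt) {
  stopifnot(inherits(c, "interface_circuit"), is.numeric(drive), dt > 0)
  mode <- match.arg(mode)
  if (mode == "voltage") {
    tau_eff <- c$Cdl * c$Rs * c$Zf / (c$Rs + c$Zf)
    if (dt > tau_eff / 10)
      stop("dt = ", dt, " s too coarse for voltage mode (tau_eff = ",
           signif(tau_eff, 3), " s); use dt <= tau_eff/10")
  }
  out <- interface_ode_cpp(drive, Zf = c$Zf, Cdl = c$Cdl, Rs = c$Rs,
                           voltage_mode = (mode == "voltage"), dt = dt)
  out
}

#' Stimulation coupling coefficients
#'
#' The triplet `(k1, k2, k3)` maps tissue current to additive membrane
#' polarization of the granule cells (GC), fast somatic inhibitory
#' interneurons (IFSI) and slow dendritic inhibitory interneurons (ISDI)
#' respectively, in mV per uA.  The sign encodes the polarization direction;
#' `(0, 0, 0)` is no stimulation.
#'
#' Two conventions are shipped as presets (see [triplet_preset()]): the
#' published condition triplets, cathodal `(30, 5, -5)` and anodal
#' `(-30, 5, 5)`, and the "suppressive" orientation — GC hyperpolarized,
#' ISDI depolarized — that minimizes discharge duration in the coupling
#' cartography.
#'
#' @param k1,k2,k3 Coupling coefficients (mV/uA), finite.
#' @return An object of class `coupling_triplet`.
#' @export
coupling_triplet <- function(k1, k2, k3) {
  stopifnot(is.finite(k1), is.finite(k2), is.finite(k3))
  structure(list(k1 = k1, k2 = k2, k3 = k3), class = "coupling_triplet")
}

#' Condition-specific coupling presets
#'
#' Two families of presets are shipped.  `"cathodal"` (`(30, 5, -5)`) and
#' `"anodal"` (`(-30, 5, 5)`) are the published condition triplets; note
#' the sign ambiguity discussed in [coupling_triplet()]: the published
#' account associates discharge suppression with granule-cell
#' hyperpolarization plus depolarization of dendrite-targeting
#' interneurons, which is numerically the anodal triplet under this
#' convention.  `"suppressive"` (`(-10, 5, 1)`) and `"excitatory"`
#' (`(10, 5, -1)`) are the corresponding pure orientations scaled to this
#' model's operating point, as mapped by [sweep_triplets()]: the
#' interneuron populations sit on a narrow stretch of their sigmoid, so
#' dendritic-interneuron couplings beyond a couple of mV/uA saturate the
#' response in either direction, and the cartography is informative at
#' moderate `|k1|` and small `|k3|`.
#'
#' @param name Preset name.
#' @return A [coupling_triplet()].
#' @export
triplet_preset <- function(name = c("cathodal", "anodal", "suppressive",
                                    "excitatory")) {
  name <- match.arg(name)
  switch(name,
         cathodal = coupling_triplet(30, 5, -5),
         anodal = coupling_triplet(-30, 5, 5),
         suppressive = coupling_triplet(-10, 5, 1),
         excitatory = coupling_triplet(10, 5, -1))
}

#' Per-population membrane offsets from a tissue current
#'
#' Linear coupling: `dVj(t) = kj * i(t)` for each population.  Offsets are
#' identically zero wherever the current is zero (outside stimulation
#' epochs).
#'
#' @param k A [coupling_triplet()] (mV/uA).
#' @param i Tissue current trace (uA).
#' @return List of numeric vectors `dv1`, `dv2`, `dv3` (mV), suitable for
#'   the `offsets` argument of [simulate_lfp()].
#' @examples
#' membrane_offsets(triplet_preset("cathodal"), i = c(0, 1, 1, 0))
#' @export
membrane_offsets <- function(k, i) {
  stopifnot(inherits(k, "coupling_triplet"), is.numeric(i))
  list(dv1 = k$k1 * i, dv2 = k$k2 * i, dv3 = k$k3 * i)
}

#' Stimulation protocol container
#'
#' @param onset,duration,amplitude Equal-length numeric vectors: epoch onset
#'   times (s), durations (s) and current amplitudes (uA, > 0).  Epochs must
#'   not overlap.
#' @param polarity `"anodal"` or `"cathodal"`; applied as a global sign on
#'   the drive (+1 anodal, -1 cathodal) when a signed drive is requested.
#' @param mode Drive mode, `"current"` (default; the stimulator holds the
#'   amplitude) or `"voltage"`.
#' @return An object of class `stim_protocol` (a data frame of epochs with
#'   attributes `polarity` and `mode`).
#' @export
stim_protocol <- function(onset, duration, amplitude,
                          polarity = c("anodal", "cathodal"),
                          mode = c("current", "voltage")) {
  polarity <- match.arg(polarity)
  mode <- match.arg(mode)
  stopifnot(length(onset) == length(duration),
            length(onset) == length(amplitude),
            all(duration > 0), all(amplitude > 0))
  o <- order(onset)
  onset <- onset[o]; duration <- duration[o]; amplitude <- amplitude[o]
  if (length(onset) > 1 &&
      any(onset[-1] < (onset + duration)[-length(onset)]))
    stop("stimulation epochs overlap")
  structure(data.frame(onset = onset, duration = duration,
                       amplitude = amplitude),
            polarity = polarity, mode = mode,
            class = c("stim_protocol", "data.frame"))
}

#' Published stimulation protocols
#'
#' `"protocol1"` (polarity study): two sub-sessions separated by one hour,
#' each of 4 epochs of 1 uA for 50 s separated by 300 s; polarity is
#' inverted in the second sub-session (epochs carry a `sub_session` column
#' and a `sign` column, +1 then -1).  `"protocol2"` (time-course study):
#' 1 h pre-stimulation, then 11 epochs of 1 uA for 50 s every 5 minutes,
#' then 1 h post-stimulation.
#'
#' @param kind `"protocol1"` or `"protocol2"`.
#' @param amplitude Epoch current (uA).
#' @param t0 Session start time of the first sub-session / pre block (s).
#' @return A [stim_protocol()]; `protocol1` has 8 epochs, `protocol2` 11.
#'   For `protocol2` the attribute `blocks` gives the pre/per/post block
#'   bounds (s).
#' @examples
#' nrow(build_protocol("protocol1"))   # 8
#' nrow(build_protocol("protocol2"))   # 11
#' @export
build_protocol <- function(kind = c("protocol1", "protocol2"),
                           amplitude = 1, t0 = 0) {
  kind <- match.arg(kind)
  if (kind == "protocol1") {
    # 4 epochs per sub-session: 50 s on, 300 s gap between epoch starts
    sub1 <- t0 + (0:3) * 350
    sub2 <- t0 + max(sub1) + 50 + 3600 + (0:3) * 350
    p <- stim_protocol(c(sub1, sub2), rep(50, 8), rep(amplitude, 8))
    p$sub_session <- rep(1:2, each = 4)
    p$sign <- rep(c(1, -1), each = 4)
    p
  } else {
    onsets <- t0 + 3600 + (0:10) * 300
    p <- stim_protocol(onsets, rep(50, 11), rep(amplitude, 11))
    p$sub_session <- 1L
    p$sign <- 1
    attr(p, "blocks") <- data.frame(
      block = c("pre", "per", "post"),
      from = c(t0, t0 + 3600, t0 + 3600 + 10 * 300 + 50),
      to = c(t0 + 3600, t0 + 3600 + 10 * 300 + 50,
             t0 + 3600 + 10 * 300 + 50 + 3600))
    p
  }
}

#' Sampled drive waveform of a protocol
#'
#' Rectangular current (or voltage) drive: epoch amplitude inside epochs,
#' zero elsewhere.  The per-epoch `sign` column (if present) and the
#' protocol polarity are applied as signs.
#'
#' @param protocol A [stim_protocol()].
#' @param fs Sampling rate (Hz).
#' @param duration Waveform length (s); default covers the whole protocol.
#' @param signed Apply polarity/sub-session signs (default `TRUE`).
#' @return Numeric drive vector of length `round(duration * fs)`.
#' @export
protocol_drive <- function(protocol, fs, duration = NULL, signed = TRUE) {
  stopifnot(inherits(protocol, "stim_protocol"), fs > 0)
  pol_sign <- if (attr(protocol, "polarity") == "cathodal") -1 else 1
  if (is.null(duration)) duration <- max(protocol$onset + protocol$duration)
  n <- round(duration * fs)
  out <- numeric(n)
  for (e in seq_len(nrow(protocol))) {
    i0 <- max(1L, floor(protocol$onset[e] * fs) + 1L)
    i1 <- min(n, ceiling((protocol$onset[e] + protocol$duration[e]) * fs))
    if (i1 < i0) next
    epoch_sign <- if (is.null(protocol$sign)) 1 else protocol$sign[e]
    s <- if (signed) pol_sign * epoch_sign else 1
    out[i0:i1] <- s * protocol$amplitude[e]
  }
  out
}
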