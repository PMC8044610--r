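#' Idealized echo-delay geometry
#'
#' Collinear source-listener-reflector idealization of a click-echo setup:
#' a loudspeaker between the listener's ears and a reflecting disk, all on
#' one line. The interclick interval (ICI, or echo delay) is the arrival
#' difference between the direct click and its reflection,
#' \deqn{\mathrm{ICI} = 1000 \cdot 2 (d_{disk} - d_{speaker}) / v \;\mathrm{ms},}
#' because the reflected path exceeds the direct path by twice the
#' speaker-to-disk distance. A small lateral offset of the disk (such as the
#' 18 degrees used when two disks flank the rail) changes path lengths by
#' well under 5% and is ignored here.
#'
#' @param ear_to_disk_m Listener-to-disk distance (m).
#' @param ear_to_speaker_m Listener-to-speaker distance (m), speaker between
#'   listener and disk; `0 <= ear_to_speaker_m < ear_to_disk_m`.
#' @param speed_of_sound_m_s Speed of sound (m/s); 343 is dry air at 20 C.
#' @return Echo delay in milliseconds.
#' @examples
#' predicted_ici(2.0, 0.3)
#' ici_slope() # about 5.8 ms per meter of reflector distance
#' @export
predicted_ici <- function(ear_to_disk_m, ear_to_speaker_m = 0,
                          speed_of_sound_m_s = 343) {
  if (any(!is.finite(ear_to_disk_m)) || any(!is.finite(ear_to_speaker_m))) {
    stop("distances must be finite", call. = FALSE)
  }
  if (any(ear_to_speaker_m < 0) || any(ear_to_speaker_m > ear_to_disk_m)) {
    stop("need 0 <= ear_to_speaker_m <= ear_to_disk_m (speaker between ",
         "listener and disk)", call. = FALSE)
  }
  if (any(speed_of_sound_m_s <= 0)) {
    stop("`speed_of_sound_m_s` must be positive", call. = FALSE)
  }
  1000 * 2 * (ear_to_disk_m - ear_to_speaker_m) / speed_of_sound_m_s
}

#' Echo-delay slope per meter of reflector distance
#'
#' The derivative of [predicted_ici()] with respect to disk distance:
#' `1000 * 2 / speed` ms per meter — about 5.8 ms/m at 343 m/s (roughly
#' 6 ms/m), the rate at which the echo delay grows as a reflector recedes.
#'
#' @inheritParams predicted_ici
#' @return Slope in ms per meter.
#' @export
ici_slope <- function(speed_of_sound_m_s = 343) {
  if (any(!is.finite(speed_of_sound_m_s)) || any(speed_of_sound_m_s <= 0)) {
    stop("`speed_of_sound_m_s` must be positive", call. = FALSE)
  }
  1000 * 2 / speed_of_sound_m_s
}
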