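#' Instrument simulation parameters
#'
#' Shared configuration for the NTA and DLS forward models. Defaults are
#' water at 25 C, a 30 fps camera, tracks averaging 30 frames with a
#' 10-frame acceptance filter, and a 1e-7 mL observation volume — a
#' field-of-view scale at which typical working dilutions put tens to
#' hundreds of particles in view, the working range of particle-tracking
#' instruments.
#'
#' @param temperature_K Temperature in kelvin.
#' @param viscosity_Pa_s Medium dynamic viscosity in Pa s.
#' @param frame_interval_s Camera frame interval in seconds.
#' @param track_length_mean Mean track length in frames.
#' @param min_track_length Minimum frames for a track to enter the size
#'   estimate.
#' @param sampling_volume_ml Observation volume (field of view x depth), mL.
#' @param n_frames Frames in the recorded video.
#' @param dilution_factor Fold-dilution applied before measurement (>= 1);
#'   concentration estimates are corrected back by this factor.
#' @param seed Optional integer seed for the simulators.
#' @return A list of class `"instrument_config"`.
#' @export
instrument_config <- function(temperature_K = 298.15,
                              viscosity_Pa_s = 8.9e-4,
                              frame_interval_s = 1 / 30,
                              track_length_mean = 30,
                              min_track_length = 10,
                              sampling_volume_ml = 1e-7,
                              n_frames = 150,
                              dilution_factor = 1,
                              seed = NULL) {
  for (nm in c("temperature_K", "viscosity_Pa_s", "frame_interval_s",
               "track_length_mean", "min_track_length", "sampling_volume_ml",
               "n_frames")) {
    check_positive(get(nm), nm)
  }
  if (dilution_factor < 1) abort_domain("`dilution_factor` must be >= 1.")
  structure(
    list(temperature_K = temperature_K, viscosity_Pa_s = viscosity_Pa_s,
         frame_interval_s = frame_interval_s,
         track_length_mean = track_length_mean,
         min_track_length = min_track_length,
         sampling_volume_ml = sampling_volume_ml, n_frames = n_frames,
         dilution_factor = dilution_factor, seed = seed),
    class = "instrument_config"
  )
}

#' Stokes-Einstein diffusion coefficient
#'
#' D = k_B T / (3 pi eta d) for a sphere of hydrodynamic diameter d in a
#' medium of viscosity eta at temperature T.
#'
#' @param diameter_nm Hydrodynamic diameter in nm.
#' @param temperature_K Temperature in kelvin.
#' @param viscosity_Pa_s Dynamic viscosity in Pa s.
#' @return Diffusion coefficient in m^2/s.
#' @examples
#' stokes_einstein(100) # ~4.91e-12 m^2/s in water at 25 C
#' @export
stokes_einstein <- function(diameter_nm, temperature_K = 298.15,
                            viscosity_Pa_s = 8.9e-4) {
  check_positive(diameter_nm, "diameter_nm")
  check_positive(temperature_K, "temperature_K")
  check_positive(viscosity_Pa_s, "viscosity_Pa_s")
  BOLTZMANN * temperature_K / (3 * pi * viscosity_Pa_s * diameter_nm * NM_TO_M)
}

#' Hydrodynamic diameter from a diffusion coefficient
#'
#' Inverse of [stokes_einstein()].
#'
#' @param diffusion_m2_s Diffusion coefficient in m^2/s.
#' @inheritParams stokes_einstein
#' @return Diameter in nm.
#' @export
diameter_from_diffusion <- function(diffusion_m2_s, temperature_K = 298.15,
                                    viscosity_Pa_s = 8.9e-4) {
  check_positive(diffusion_m2_s, "diffusion_m2_s")
  BOLTZMANN * temperature_K /
    (3 * pi * viscosity_Pa_s * diffusion_m2_s) / NM_TO_M
}
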