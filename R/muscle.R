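#' Physiological cross-sectional area of a muscle
#'
#' PCSA = mass / (density * fibre length), the cross-section perpendicular
#' to the fibres and hence independent of contractile status. The default
#' muscle density is 1060 kg/m^3.
#'
#' @param muscle_mass Muscle mass (kg, > 0).
#' @param fibre_length Mean fibre length (m, > 0).
#' @param density Muscle density (kg/m^3).
#' @return PCSA in m^2.
#' @examples
#' pcsa(0.01, 0.02)   # 4.717e-4 m^2
#' @export
pcsa <- function(muscle_mass, fibre_length, density = 1060) {
  check_positive(muscle_mass, "muscle_mass")
  check_positive(fibre_length, "fibre_length")
  check_positive(density, "density")
  muscle_mass / (density * fibre_length)
}

#' Force-generating capacity from summed PCSAs
#'
#' Multiplies the summed physiological cross-sectional areas of a limb's
#' extensor muscles by an assumed maximum isometric muscle stress
#' (0.3 MPa by default).
#'
#' @param pcsa_values Non-empty vector of PCSAs (m^2, > 0).
#' @param stress Muscle stress (Pa, >= 0).
#' @return Force in newtons.
#' @export
force_capacity <- function(pcsa_values, stress = 0.3e6) {
  if (length(pcsa_values) == 0) stop("empty PCSA set", call. = FALSE)
  check_positive(pcsa_values, "pcsa_values")
  check_nonnegative(stress, "stress")
  stress * sum(pcsa_values)
}

#' Express a force capacity in body weights
#'
#' @param force Force (N).
#' @param BM Body mass (kg, > 0).
#' @param g Gravitational acceleration (m/s^2).
#' @return Capacity in BW. Under isometric growth PCSA scales as BM^(2/3),
#'   so capacity in BW falls as BM^(-1/3): smaller animals are relatively
#'   stronger.
#' @export
capacity_in_bw <- function(force, BM, g = 9.81) {
  check_positive(BM, "BM"); check_positive(g, "g")
  force / (BM * g)
}

#' Per-limb force-generating capacity table
#'
#' Computes each piglet's summed extensor PCSA per limb and the resulting
#' force capacity in newtons and body weights.
#'
#' @param muscles Data frame (`piglet_id`, `limb`, `muscle_id`, `mass_kg`,
#'   `fibre_length_m`).
#' @param piglets Data frame with `piglet_id` and `birth_mass_kg`.
#' @param density Muscle density (kg/m^3).
#' @param stress Muscle stress (Pa).
#' @param g Gravitational acceleration (m/s^2).
#' @return Data frame: `piglet_id`, `limb`, `total_pcsa_m2`,
#'   `force_capacity_n`, `capacity_bw`.
#' @export
limb_capacity_table <- function(muscles, piglets, density = 1060,
                                stress = 0.3e6, g = 9.81) {
  stopifnot(is.data.frame(muscles), is.data.frame(piglets))
  areas <- pcsa(muscles$mass_kg, muscles$fibre_length_m, density)
  agg <- stats::aggregate(areas,
                          by = list(piglet_id = muscles$piglet_id,
                                    limb = muscles$limb),
                          FUN = sum)
  names(agg)[3] <- "total_pcsa_m2"
  agg$force_capacity_n <- stress * agg$total_pcsa_m2
  bm <- piglets$birth_mass_kg[match(agg$piglet_id, piglets$piglet_id)]
  agg$capacity_bw <- capacity_in_bw(agg$force_capacity_n, bm, g)
  agg[order(agg$piglet_id, agg$limb), ]
}
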