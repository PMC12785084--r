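# Macroscopic morphometry: immersion volume with saline-density correction,
# and the derived indices (T-index, GSI). Unit handling is explicit
# throughout: every index records the unit convention it was computed under,
# because the indices are not dimensionless and silently mixed units are a
# classic source of irreproducible tables.

.mass_to_g <- c(mg = 1e-3, g = 1, kg = 1e3)
.len_to_mm <- c(mm = 1, cm = 10, m = 1000)

#' Testis volume by saline immersion
#'
#' Scherle's method: the mass of displaced isotonic saline divided by the
#' saline density (1.0048 g/cm^3) gives the fresh organ volume.
#'
#' @param displaced_mass Displaced mass in grams (> 0).
#' @param saline_density Saline density in g/cm^3.
#' @return Volume in cm^3.
#' @export
immersion_volume <- function(displaced_mass, saline_density = 1.0048) {
  if (any(displaced_mass <= 0)) stop("displaced mass must be positive")
  stopifnot(saline_density > 0)
  displaced_mass / saline_density
}

#' Testicular index
#'
#' `T-index = length x width / body weight`. The conventional units are
#' millimetres for the linear measurements and kilograms for body weight
#' (the only convention under which the index has its usual magnitude of a
#' few tens); other units are converted and the convention is recorded in
#' the result's attributes.
#'
#' @param length,width Testis length and width.
#' @param bw Body weight.
#' @param length_unit,width_unit `"mm"`, `"cm"` or `"m"`.
#' @param bw_unit `"mg"`, `"g"` or `"kg"`.
#' @return T-index (mm^2/kg) with attribute `units`.
#' @export
t_index <- function(length, width, bw,
                    length_unit = "mm", width_unit = length_unit,
                    bw_unit = "kg") {
  stopifnot(all(length > 0), all(width > 0), all(bw > 0),
            length_unit %in% names(.len_to_mm),
            width_unit %in% names(.len_to_mm),
            bw_unit %in% names(.mass_to_g))
  l_mm <- length * .len_to_mm[[length_unit]]
  w_mm <- width * .len_to_mm[[width_unit]]
  bw_kg <- bw * .mass_to_g[[bw_unit]] / 1000
  out <- l_mm * w_mm / bw_kg
  attr(out, "units") <- "mm^2/kg (inputs converted to mm and kg)"
  out
}

#' Gonadosomatic index
#'
#' `GSI = testis weight / body weight x 100`, with both masses expressed in
#' the same unit before the ratio is taken; the conversion applied is
#' recorded in the result's attributes. The index is scale-invariant once
#' units agree.
#'
#' @param tw Testis weight.
#' @param bw Body weight.
#' @param tw_unit,bw_unit Mass units (`"mg"`, `"g"`, `"kg"`).
#' @return GSI (percent of body mass) with attribute `units`.
#' @export
gsi <- function(tw, bw, tw_unit = "g", bw_unit = "g") {
  stopifnot(all(tw >= 0),
            tw_unit %in% names(.mass_to_g), bw_unit %in% names(.mass_to_g))
  if (any(bw <= 0)) stop("body weight must be positive")
  out <- 100 * (tw * .mass_to_g[[tw_unit]]) / (bw * .mass_to_g[[bw_unit]])
  attr(out, "units") <- sprintf("%% (tw in %s, bw in %s, both converted to g)",
                                tw_unit, bw_unit)
  out
}

#' Add derived morphometric indices to an animal table
#'
#' Appends `t_index` (length x width in mm over BW in kg) and `gsi`
#' (TW and BW both in grams) columns to a cohort animal table with columns
#' `bw_kg`, `tw_g`, `length_cm`, `width_cm`.
#'
#' @param animals Animal data frame (see [generate_cohort()]).
#' @return The table with the two derived columns appended.
#' @export
derive_indices <- function(animals) {
  stopifnot(all(c("bw_kg", "tw_g", "length_cm", "width_cm") %in%
                  names(animals)))
  animals$t_index <- as.numeric(t_index(animals$length_cm, animals$width_cm,
                                        animals$bw_kg,
                                        length_unit = "cm", bw_unit = "kg"))
  animals$gsi <- as.numeric(gsi(animals$tw_g, animals$bw_kg,
                                tw_unit = "g", bw_unit = "kg"))
  animals
}
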