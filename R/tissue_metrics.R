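#' Intravascular solute mass
#'
#' Circulating mass of a serum solute (albumin, total protein): serum
#' concentration times the simultaneous plasma volume, normalised to body
#' weight. Note that a group mean of per-animal masses generally differs from
#' the product of the group-mean concentration and group-mean plasma volume;
#' masses are computed per animal.
#'
#' @param conc_g_l serum concentration, g/l (>= 0).
#' @param pv_ml simultaneous plasma volume, ml (> 0).
#' @param weight_kg body weight, kg.
#' @return Solute mass in g per kg body weight.
#' @export
#' @examples
#' solute_mass(31.4, 60.9 * 42, 42) # ~1.91 g/kg
solute_mass <- function(conc_g_l, pv_ml, weight_kg) {
  stop_unless(is.numeric(conc_g_l) && all(conc_g_l >= 0, na.rm = TRUE),
              "concentration must be non-negative")
  stop_unless(all(pv_ml > 0), "plasma volume must be positive")
  stop_unless(is.numeric(weight_kg) && all(weight_kg > 0),
              "weight must be positive")
  conc_g_l * (pv_ml / 1000) / weight_kg
}

#' Regional blood flow by the reference-sample microsphere method
#'
#' Microspheres injected into the left ventricle lodge in capillaries in
#' proportion to regional flow; a simultaneous constant-rate arterial
#' withdrawal provides the reference. Tissue flow is
#' `(n_spheres / n_ref) * q_ref`, expressed per 100 g tissue.
#'
#' @param n_spheres sphere count in the tissue sample (>= 0).
#' @param sample_mass_g tissue sample mass, g (> 0).
#' @param n_ref sphere count in the reference blood sample (> 0).
#' @param q_ref_ml_min reference withdrawal rate, ml/min (> 0).
#' @return Flow in ml/min/100 g.
#' @export
#' @examples
#' microsphere_flow(500, 2.5, 10000, 2) # 4 ml/min/100 g
microsphere_flow <- function(n_spheres, sample_mass_g, n_ref, q_ref_ml_min) {
  stop_unless(all(n_spheres >= 0), "sphere counts must be non-negative")
  stop_unless(all(sample_mass_g > 0), "sample mass must be positive")
  stop_unless(all(q_ref_ml_min > 0), "reference withdrawal rate must be positive")
  if (any(n_ref <= 0)) {
    stop("no reference spheres recovered: n_ref must be positive", call. = FALSE)
  }
  (n_spheres / n_ref) * q_ref_ml_min * 100 / sample_mass_g
}

#' Total tissue water by wet/dry gravimetry
#'
#' Water content of a tissue sample as grams of water per gram dry weight:
#' `(wet - dry) / dry`, the weight lost on drying to constant weight over the
#' residual dry mass. Values outside 0-10 g/g are physiologically implausible
#' and trigger a warning.
#'
#' @param wet_mg,dry_mg sample weight before and after drying, mg;
#'   `wet_mg >= dry_mg > 0`.
#' @return Total tissue water, g water per g dry weight.
#' @export
#' @examples
#' tissue_water(621, 100) # 5.21 g/g, e.g. lung
tissue_water <- function(wet_mg, dry_mg) {
  stop_unless(all(dry_mg > 0), "dry mass must be positive")
  if (any(wet_mg < dry_mg)) {
    stop("wet mass below dry mass: weighing or labelling error", call. = FALSE)
  }
  ttw <- (wet_mg - dry_mg) / dry_mg
  if (any(ttw > 10)) {
    warning("tissue water above 10 g/g dry weight; check sample weights")
  }
  ttw
}

#' Derived hemodynamic indices
#'
#' Systemic and pulmonary vascular resistance in conventional dyne units
#' (`80 * pressure gradient / cardiac output`), cerebral perfusion pressure
#' (`MAP - ICP`) and the cerebral microdialysate lactate/pyruvate ratio.
#' Lactate is given in mmol/l and pyruvate in umol/l as assays report them;
#' with `lp_units = "consistent"` (default) pyruvate is converted to mmol/l
#' before dividing, with `"raw"` the concentrations are divided as given.
#'
#' @param map,cvp_ra,mpap,pcwp,icp pressures, mmHg (mean arterial, right-atrial
#'   central venous, mean pulmonary arterial, pulmonary capillary wedge,
#'   intracranial).
#' @param co cardiac output, l/min (> 0).
#' @param lactate_mmol_l,pyruvate_umol_l optional microdialysate
#'   concentrations.
#' @param lp_units `"consistent"` or `"raw"`, see Details.
#' @return `data.frame` with `svr`, `pvr` (dynes s cm^-5), `cpp` (mmHg) and
#'   `lp_ratio` (NA when metabolites are not supplied).
#' @export
#' @examples
#' derived_hemodynamics(65.8, 8.0, 20.0, 11.0, 16.3, co = 5.1)
derived_hemodynamics <- function(map, cvp_ra, mpap, pcwp, icp, co,
                                 lactate_mmol_l = NULL, pyruvate_umol_l = NULL,
                                 lp_units = c("consistent", "raw")) {
  lp_units <- match.arg(lp_units)
  if (any(co <= 0)) {
    stop("vascular resistance undefined: cardiac output must be positive",
         call. = FALSE)
  }
  lp <- NA_real_
  if (!is.null(lactate_mmol_l) && !is.null(pyruvate_umol_l)) {
    stop_unless(all(pyruvate_umol_l > 0), "pyruvate must be positive")
    lp <- if (lp_units == "consistent") {
      lactate_mmol_l / (pyruvate_umol_l / 1000)
    } else {
      lactate_mmol_l / pyruvate_umol_l
    }
  }
  data.frame(svr = 80 * (map - cvp_ra) / co,
             pvr = 80 * (mpap - pcwp) / co,
             cpp = map - icp,
             lp_ratio = lp)
}

#' Percent change from baseline
#'
#' `100 (baseline - end) / baseline`, positive for a reduction. Group values
#' are the mean of per-animal percentages, not the percentage of group means —
#' the two differ whenever baseline varies between animals.
#'
#' @param baseline,end paired per-animal values; `baseline` must be non-zero.
#' @return Per-animal percent reductions (vector of `length(baseline)`).
#' @seealso [group_percent_change()]
#' @export
percent_change <- function(baseline, end) {
  stop_unless(length(baseline) == length(end),
              "baseline and end must be paired")
  if (any(baseline == 0)) {
    stop("percent change undefined for zero baseline", call. = FALSE)
  }
  100 * (baseline - end) / baseline
}

#' Group summary of per-animal percent change
#'
#' @inheritParams percent_change
#' @return `data.frame` with `mean`, `sd`, `n` of per-animal percent changes.
#' @export
group_percent_change <- function(baseline, end) {
  pc <- percent_change(baseline, end)
  data.frame(mean = mean(pc), sd = stats::sd(pc), n = length(pc))
}
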