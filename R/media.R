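# molar mass of nitrogen, g/mol
N_MOLAR_MASS <- 14.007

#' Specify a carbon substrate for C:N medium design
#'
#' Concentration refers to the supplied form (e.g. the sodium salt for
#' acetate and gluconate), so `molar_mass` must be the molar mass of that
#' form. `acetyl_coa_equiv` is the assumed number of acetyl-CoA molecules
#' generated per molecule of substrate through central metabolism; it is a
#' user-supplied constant, not inferred from pathway databases.
#'
#' @param name substrate label
#' @param conc concentration (> 0)
#' @param molar_mass g/mol of the supplied form (> 0)
#' @param acetyl_coa_equiv acetyl-CoA equivalents per molecule (>= 0)
#' @param n_atoms nitrogen atoms per molecule (for substrates such as
#'   N-acetylglucosamine)
#' @param unit `"g_per_L"` or `"mol_per_L"`
#' @return object of class `substrate_spec`
#' @export
substrate_spec <- function(name, conc, molar_mass, acetyl_coa_equiv,
                           n_atoms = 0, unit = c("g_per_L", "mol_per_L")) {
  unit <- match.arg(unit)
  if (!is.finite(conc) || conc <= 0)
    stop_cfg("substrate_spec %s: conc must be > 0", name)
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop_cfg("substrate_spec %s: molar_mass must be > 0", name)
  if (!is.finite(acetyl_coa_equiv) || acetyl_coa_equiv < 0)
    stop_cfg("substrate_spec %s: acetyl_coa_equiv must be >= 0", name)
  structure(list(name = name, conc = conc, molar_mass = molar_mass,
                 acetyl_coa_equiv = acetyl_coa_equiv, n_atoms = n_atoms,
                 unit = unit),
            class = "substrate_spec")
}

#' Specify a medium's nitrogen sources
#'
#' @param nitrogen_sources data frame with columns `name`, `conc_g_per_L`,
#'   `n_mass_fraction` (g N per g of the source)
#' @param include_substrate_nitrogen also count nitrogen intrinsic to the
#'   carbon substrate (off by default: the conventional ratio treats the
#'   nitrogen source as the sole N supply)
#' @return object of class `medium_spec`
#' @export
medium_spec <- function(nitrogen_sources, include_substrate_nitrogen = FALSE) {
  ns <- as.data.frame(nitrogen_sources)
  need <- c("name", "conc_g_per_L", "n_mass_fraction")
  if (!all(need %in% names(ns)))
    stop_cfg("medium_spec: nitrogen_sources needs columns %s",
             paste(need, collapse = ", "))
  if (sum(ns$conc_g_per_L * ns$n_mass_fraction) <= 0)
    stop_cfg("medium_spec: total nitrogen must be > 0")
  structure(list(nitrogen_sources = ns,
                 include_substrate_nitrogen =
                   isTRUE(include_substrate_nitrogen)),
            class = "medium_spec")
}

#' Preset PHA-production media
#'
#' `mm_pha1()` carries 0.20 g/L NH4Cl as sole nitrogen source (nitrogen
#' mass fraction 14.007/53.491). `mm_pha2()` replaces it with 1.0 g/L yeast
#' extract; yeast-extract nitrogen content is not a defined quantity, and
#' the default mass fraction of 0.105 g N/g is the package's calibrated
#' assumption (configurable).
#'
#' @param ye_n_fraction yeast-extract nitrogen mass fraction (mm_pha2 only)
#' @return a [medium_spec()]
#' @export
mm_pha1 <- function() {
  medium_spec(data.frame(name = "NH4Cl", conc_g_per_L = 0.20,
                         n_mass_fraction = N_MOLAR_MASS / 53.491))
}

#' @rdname mm_pha1
#' @export
mm_pha2 <- function(ye_n_fraction = 0.105) {
  medium_spec(data.frame(name = "yeast extract", conc_g_per_L = 1.0,
                         n_mass_fraction = ye_n_fraction))
}

# moles of nitrogen per litre supplied by the medium (+ substrate if asked)
medium_n_moles <- function(medium, sub = NULL) {
  ns <- medium$nitrogen_sources
  n <- sum(ns$conc_g_per_L * ns$n_mass_fraction) / N_MOLAR_MASS
  if (!is.null(sub) && medium$include_substrate_nitrogen) {
    mol <- if (sub$unit == "g_per_L") sub$conc / sub$molar_mass else sub$conc
    n <- n + mol * sub$n_atoms
  }
  n
}

#' Acetyl-CoA-equivalent carbon-to-nitrogen ratio
#'
#' The design ratio is moles of acetyl-CoA equivalents supplied by the
#' carbon substrate per mole of nitrogen in the medium:
#' \deqn{\mathrm{C{:}N} = \frac{(c / M) \cdot e}{\sum_j n_j}}
#' with substrate concentration c (g/L), molar mass M, equivalents per
#' molecule e, and nitrogen source moles n_j. This is a metabolic ratio,
#' not an elemental C:N (elemental readings give values roughly three-fold
#' higher for hexoses).
#'
#' @param sub a [substrate_spec()]
#' @param medium a [medium_spec()]
#' @return list of class `cn_result`: `substrate`, `ratio`
#' @export
cn_ratio <- function(sub, medium) {
  stopifnot(inherits(sub, "substrate_spec"), inherits(medium, "medium_spec"))
  n <- medium_n_moles(medium, sub)
  if (n <= 0) stop_cfg("cn_ratio: medium supplies no nitrogen")
  mol <- if (sub$unit == "g_per_L") sub$conc / sub$molar_mass else sub$conc
  structure(list(substrate = sub$name,
                 ratio = mol * sub$acetyl_coa_equiv / n),
            class = "cn_result")
}

#' Mean and SD of C:N ratios across substrates
#' @param subs list of [substrate_spec()]
#' @param medium a [medium_spec()]
#' @return list with `mean`, `sd`, `n`, and the per-substrate `ratios`
#'   data frame
#' @export
cn_summary <- function(subs, medium) {
  if (inherits(subs, "substrate_spec")) subs <- list(subs)
  if (length(subs) < 2L)
    stop_cfg("cn_summary: need >= 2 substrates (got %d)", length(subs))
  ratios <- vapply(subs, function(s) cn_ratio(s, medium)$ratio, 1.0)
  df <- data.frame(substrate = vapply(subs, `[[`, "", "name"),
                   ratio = ratios)
  list(mean = mean(ratios), sd = sd(ratios), n = length(ratios),
       ratios = df)
}

#' Invert the C:N calculation to a substrate concentration
#'
#' Solves for the g/L concentration that achieves `target_ratio` against
#' the medium's nitrogen: `conc = target * N_moles * M / e`. Exact inverse
#' of [cn_ratio()] by construction (substrate-intrinsic nitrogen is ignored
#' here, matching the default forward calculation).
#'
#' @param target_ratio desired equivalents-to-N ratio (>= 0)
#' @param sub_template a [substrate_spec()] whose `conc` is ignored
#' @param medium a [medium_spec()]
#' @return concentration in g/L
#' @export
design_concentration <- function(target_ratio, sub_template, medium) {
  stopifnot(inherits(sub_template, "substrate_spec"),
            inherits(medium, "medium_spec"))
  if (sub_template$acetyl_coa_equiv <= 0)
    stop_cfg("design_concentration %s: acetyl_coa_equiv must be > 0",
             sub_template$name)
  if (target_ratio < 0)
    stop_cfg("design_concentration: target_ratio must be >= 0")
  n <- medium_n_moles(medium)
  target_ratio * n * sub_template$molar_mass / sub_template$acetyl_coa_equiv
}

#' Packaged reference table of the 15 screening substrates
#'
#' The carbon substrates used in the 96-well PHA production screens, with
#' assumed acetyl-CoA equivalents, supplied concentrations, and molar
#' masses of the supplied forms (sodium salts for acetate and gluconate,
#' free acids for the organic acids).
#'
#' @param as_specs return a list of [substrate_spec()] instead of the raw
#'   data frame
#' @return data frame or list of `substrate_spec`
#' @export
pha_substrates <- function(as_specs = FALSE) {
  path <- system.file("extdata", "pha_substrates.csv",
                      package = "phascreen", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!as_specs) return(df)
  lapply(seq_len(nrow(df)), function(i)
    substrate_spec(df$name[i], df$conc_g_per_L[i], df$molar_mass[i],
                   df$acetyl_coa_equiv[i], df$n_atoms[i]))
}
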