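#' Built-in gene-network models
#'
#' Returns one of the case-study reaction networks shipped with the package,
#' complete with parameter bounds and reference ("true") parameter values
#' used for synthetic-data generation:
#'
#' * `"ecoli_rna"` — bursty transcription in *E. coli*: a promoter switches
#'   between a silent (`DNA_S`) and an activated (`DNA_A`) configuration with
#'   rates `k1`/`k2`, and the activated form transcribes a reporter mRNA at
#'   rate `k3`. mRNA counts are the observable (single-molecule fluorescence
#'   reporters make them countable per cell). True values follow the
#'   switching rates fitted in the original single-cell mRNA study (ON rate
#'   about 1/37 per minute, OFF rate about 1/6 per minute, transcription
#'   about 0.4 per minute during the ON state); all bounds are `[0, 5]`.
#' * `"yegfp_reduced"` — reduced yeast galactose-uptake expression model: two
#'   uncoupled transcription/translation/decay cascades (yEGFP and TetR
#'   reporters), 8 irreversible reactions, 4 states, 8 parameters. The
#'   promoter configurations of the full model are assumed at
#'   pseudo-equilibrium, so the effective transcription rates are constants.
#'   This effective encoding is a synthetic stand-in chosen to match the
#'   published structure counts and parameter roster.
#' * `"yegfp_full"` — the same pathway with explicit promoter configurations:
#'   three active configurations (free, intermediate, pre-initiation) and two
#'   TetR-repressed configurations, reversible transitions among them plus
#'   TetR binding/release, and the 8 irreversible synthesis/decay reactions
#'   (18 reactions, 9 states, 15 parameters). Also a synthetic stand-in with
#'   the published dimensions and parameter names.
#' * `"toggle_switch"` — the two-repressor genetic toggle switch with Hill
#'   propensities: `a1 = alpha1/(1 + v^beta)`, `a2 = u`,
#'   `a3 = alpha2/(1 + w^gamma)` with `w = u/(1 + IPTG/K)^eta`, `a4 = v`,
#'   where `u` is the LacI repressor and `v` the GFP-tagged second repressor.
#'   Degradation rate constants are unity (dimensionless time), so all six
#'   estimated parameters enter the synthesis propensities.
#' * `"birth_death_test"` — an immigration–death process (constant birth `k`,
#'   linear death `gamma * X`) whose Poisson transient and stationary laws
#'   are known in closed form; used throughout the test suite.
#'
#' @param name Model identifier (see above).
#' @param iptg Inducer concentration in mol/L for `"toggle_switch"`
#'   (default `6e-5`).
#' @return A [reaction_network] with `true_params` metadata.
#' @export
builtin_model <- function(name, iptg = 6e-5) {
  models <- c("ecoli_rna", "yegfp_reduced", "yegfp_full", "toggle_switch",
              "birth_death_test")
  if (!is.character(name) || length(name) != 1L || !name %in% models) {
    stop("unknown model '", name, "'; available models: ",
         paste(models, collapse = ", "), call. = FALSE)
  }
  switch(name,
    ecoli_rna = model_ecoli_rna(),
    yegfp_reduced = model_yegfp_reduced(),
    yegfp_full = model_yegfp_full(),
    toggle_switch = model_toggle_switch(iptg),
    birth_death_test = model_birth_death()
  )
}

# Default initial state and time origin for a built-in model.
builtin_x0 <- function(name) {
  switch(name,
    ecoli_rna = c(DNA_S = 1L, DNA_A = 0L, RNA = 0L),
    yegfp_reduced = c(rna_yegfp = 0L, yEGFP = 0L, rna_tetr = 0L, TetR = 0L),
    yegfp_full = c(PC1 = 1L, PC2 = 0L, PC3 = 0L, RC1 = 0L, RC2 = 0L,
                   rna_yegfp = 0L, yEGFP = 0L, rna_tetr = 0L, TetR = 0L),
    toggle_switch = c(LacI = 0L, GFP = 0L),
    birth_death_test = c(X = 0L),
    stop("no default initial state for '", name, "'", call. = FALSE)
  )
}

model_ecoli_rna <- function() {
  reaction_network(
    species = c("DNA_S", "DNA_A", "RNA"),
    reactions = list(
      reaction("activation", c(DNA_S = -1L, DNA_A = 1L),
               prop_mass_action("k1", "DNA_S")),
      reaction("deactivation", c(DNA_A = -1L, DNA_S = 1L),
               prop_mass_action("k2", "DNA_A")),
      reaction("transcription", c(RNA = 1L),
               prop_mass_action("k3", "DNA_A"))
    ),
    parameters = list(k1 = c(0, 5), k2 = c(0, 5), k3 = c(0, 5)),
    true_params = c(k1 = 0.027, k2 = 0.167, k3 = 0.40),
    observables = "RNA",
    volume_label = "single E. coli cell"
  )
}

model_yegfp_reduced <- function() {
  reaction_network(
    species = c("rna_yegfp", "yEGFP", "rna_tetr", "TetR"),
    reactions = list(
      reaction("transcription_G", c(rna_yegfp = 1L),
               prop_mass_action("kappa_R")),
      reaction("translation_G", c(yEGFP = 1L),
               prop_mass_action("kappa_P", "rna_yegfp")),
      reaction("rna_decay_G", c(rna_yegfp = -1L),
               prop_mass_action("gamma_R", "rna_yegfp")),
      reaction("protein_decay_G", c(yEGFP = -1L),
               prop_mass_action("gamma_P", "yEGFP")),
      reaction("transcription_T", c(rna_tetr = 1L),
               prop_mass_action("kappa_Rt")),
      reaction("translation_T", c(TetR = 1L),
               prop_mass_action("kappa_Pt", "rna_tetr")),
      reaction("rna_decay_T", c(rna_tetr = -1L),
               prop_mass_action("gamma_Rt", "rna_tetr")),
      reaction("protein_decay_T", c(TetR = -1L),
               prop_mass_action("gamma_Pt", "TetR"))
    ),
    parameters = list(
      kappa_R = c(0, 5), kappa_P = c(0, 5), gamma_R = c(0, 10),
      gamma_P = c(0, 5), kappa_Rt = c(0, 5), kappa_Pt = c(0, 5),
      gamma_Rt = c(0, 10), gamma_Pt = c(0, 5)
    ),
    true_params = c(kappa_R = 1, kappa_P = 1, gamma_R = 5, gamma_P = 0.0125,
                    kappa_Rt = 0.417, kappa_Pt = 1, gamma_Rt = 3,
                    gamma_Pt = 0.0125),
    observables = c("yEGFP", "TetR"),
    volume_label = "single S. cerevisiae cell (dimensionless time)"
  )
}

model_yegfp_full <- function() {
  reaction_network(
    species = c("PC1", "PC2", "PC3", "RC1", "RC2",
                "rna_yegfp", "yEGFP", "rna_tetr", "TetR"),
    reactions = list(
      reaction("pc1_to_pc2", c(PC1 = -1L, PC2 = 1L),
               prop_mass_action("k1f", "PC1")),
      reaction("pc2_to_pc1", c(PC2 = -1L, PC1 = 1L),
               prop_mass_action("k1b", "PC2")),
      reaction("pc2_to_pc3", c(PC2 = -1L, PC3 = 1L),
               prop_mass_action("k2f", "PC2")),
      reaction("pc3_to_pc2", c(PC3 = -1L, PC2 = 1L),
               prop_mass_action("k2b", "PC3")),
      reaction("repress_pc1", c(PC1 = -1L, TetR = -1L, RC1 = 1L),
               prop_mass_action("k3f", c("PC1", "TetR"))),
      reaction("derepress_rc1", c(RC1 = -1L, PC1 = 1L, TetR = 1L),
               prop_mass_action("k3b", "RC1")),
      reaction("repress_pc2", c(PC2 = -1L, TetR = -1L, RC2 = 1L),
               prop_mass_action("k3f", c("PC2", "TetR"))),
      reaction("derepress_rc2", c(RC2 = -1L, PC2 = 1L, TetR = 1L),
               prop_mass_action("k3b", "RC2")),
      reaction("rc1_to_rc2", c(RC1 = -1L, RC2 = 1L),
               prop_mass_action("alpha", "RC1")),
      reaction("rc2_to_rc1", c(RC2 = -1L, RC1 = 1L),
               prop_mass_action("k1b", "RC2")),
      reaction("transcription_G", c(rna_yegfp = 1L),
               prop_mass_action("kappa_R", "PC3")),
      reaction("translation_G", c(yEGFP = 1L),
               prop_mass_action("kappa_P", "rna_yegfp")),
      reaction("rna_decay_G", c(rna_yegfp = -1L),
               prop_mass_action("gamma_R", "rna_yegfp")),
      reaction("protein_decay_G", c(yEGFP = -1L),
               prop_mass_action("gamma_P", "yEGFP")),
      reaction("transcription_T", c(rna_tetr = 1L),
               prop_mass_action("kappa_Rt")),
      reaction("translation_T", c(TetR = 1L),
               prop_mass_action("kappa_Pt", "rna_tetr")),
      reaction("rna_decay_T", c(rna_tetr = -1L),
               prop_mass_action("gamma_Rt", "rna_tetr")),
      reaction("protein_decay_T", c(TetR = -1L),
               prop_mass_action("gamma_Pt", "TetR"))
    ),
    parameters = list(
      k1f = c(0, 5), k1b = c(0, 5), k2f = c(0, 100), k2b = c(0, 20),
      k3f = c(0, 5), k3b = c(0, 20), alpha = c(0, 5),
      kappa_R = c(0, 5), kappa_P = c(0, 5), gamma_R = c(0, 10),
      gamma_P = c(0, 5), kappa_Rt = c(0, 5), kappa_Pt = c(0, 5),
      gamma_Rt = c(0, 10), gamma_Pt = c(0, 5)
    ),
    true_params = c(k1f = 0.42, k1b = 0.2485, k2f = 50, k2b = 10,
                    k3f = 3.032e-3, k3b = 10, alpha = 0.025,
                    kappa_R = 1, kappa_P = 1, gamma_R = 5, gamma_P = 0.0125,
                    kappa_Rt = 0.417, kappa_Pt = 1, gamma_Rt = 3,
                    gamma_Pt = 0.0125),
    observables = c("yEGFP", "TetR"),
    volume_label = "single S. cerevisiae cell (dimensionless time)"
  )
}

model_toggle_switch <- function(iptg = 6e-5) {
  stopifnot(is.numeric(iptg), iptg >= 0)
  reaction_network(
    species = c("LacI", "GFP"),
    reactions = list(
      reaction("synthesis_u", c(LacI = 1L),
               prop_hill("alpha1", "GFP", "beta")),
      reaction("degradation_u", c(LacI = -1L),
               prop_mass_action(1, "LacI")),
      reaction("synthesis_v", c(GFP = 1L),
               prop_hill("alpha2", "LacI", "gamma",
                         half_sat = "K", sat_exponent = "eta", conc = iptg)),
      reaction("degradation_v", c(GFP = -1L),
               prop_mass_action(1, "GFP"))
    ),
    parameters = list(
      alpha1 = c(0, 200), alpha2 = c(0, 20), beta = c(0, 10),
      gamma = c(0, 10), eta = c(0, 10), K = c(0, 1)
    ),
    true_params = c(alpha1 = 156.25, alpha2 = 15.6, beta = 2.5, gamma = 1,
                    eta = 2.0015, K = 6e-5),
    observables = "GFP",
    volume_label = sprintf("single E. coli cell, IPTG %g M", iptg)
  )
}

model_birth_death <- function() {
  reaction_network(
    species = "X",
    reactions = list(
      reaction("birth", c(X = 1L), prop_mass_action("k")),
      reaction("death", c(X = -1L), prop_mass_action("gamma", "X"))
    ),
    parameters = list(k = c(0, 10), gamma = c(0, 5)),
    true_params = c(k = 5, gamma = 1),
    observables = "X"
  )
}
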