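# Default model configuration for hybridcycle.
#
# This file is the single source of truth for the package defaults:
# model_config() reads it and applies any overrides on top.  Every key
# carries a provenance tag:
#   provenance: paper      -- value printed in the source publication
#   provenance: calibrated -- value chosen by this package so that the
#                             default parameter set yields a ~20 h mean
#                             cycle, cyclin A at S entry near 8% of the
#                             population maximum, and a contact-inhibited
#                             plateau near day 6 (see the methods
#                             vignette for the calibration rationale)
#
# Units: time in hours, cyclin levels in arbitrary concentration units
# (AU), mass in arbitrary units, rates in AU/h or 1/h.

# --- cyclin A ---------------------------------------------------------
ksa_basal: 5           # provenance: paper  (k'_sa = 5)
ksa_tfe: 10            # provenance: calibrated  (synthesis increment while TFE = 1)
ksa_tfb: 35            # provenance: calibrated  (synthesis increment while TFB = 1)
kda_basal: 0.25        # provenance: calibrated
kda_cdc20a: 12         # provenance: calibrated  (degradation increment while Cdc20A = 1)
kda_cdh1: 1.15         # provenance: paper  (k'_da + k'''_da = 1.4 in state 1)

# --- cyclin E ---------------------------------------------------------
kse_basal: 0.1         # provenance: calibrated
kse_tfe: 1.75          # provenance: calibrated
kde_basal: 0.25        # provenance: calibrated
kde_scf: 1.5           # provenance: calibrated  (degradation increment while SCF = 1)

# --- cyclin B ---------------------------------------------------------
ksb_basal: 1.5         # provenance: calibrated
ksb_tfb: 40            # provenance: calibrated
kdb_basal: 0.1         # provenance: calibrated
kdb_cdc20b: 2.9        # provenance: calibrated  (partial degradation at anaphase)
kdb_cdh1: 5.9          # provenance: calibrated  (faster degradation at telophase)

# --- thresholds -------------------------------------------------------
# The printed quartet is {12.5, 21.25, 3, 80}; the symbol assignment
# follows the textual bases: theta_E acts on the amount [CycE]*M,
# theta_A on the concentration [CycA], theta_B' / theta_B'' on the
# concentration [CycB] (up / down crossings).
theta_e: 21.25         # provenance: paper  (assignment: calibrated)
theta_a: 12.5          # provenance: paper  (assignment: calibrated)
theta_b1: 80           # provenance: paper  (assignment: calibrated)
theta_b2: 3            # provenance: paper  (assignment: calibrated)

# --- stochastic waiting-time means lambda_i (h) -----------------------
lambda_1: 2            # provenance: paper  (exponential mean in G1a)
lambda_2: 0            # provenance: paper  (no stochastic component out of state 2)
lambda_3: 0            # provenance: calibrated  (keeps S entry at the theta_A crossing)
lambda_4: 0.5          # provenance: calibrated
lambda_5: 0.5          # provenance: calibrated
lambda_6: 0.5          # provenance: calibrated
lambda_7: 0.5          # provenance: calibrated
lambda_8: 0.5          # provenance: calibrated
lambda_9: 0.5          # provenance: calibrated

# --- timers -----------------------------------------------------------
t_det_4: 7             # provenance: paper  (DNA synthesis requires at least 7 h)

# --- growth -----------------------------------------------------------
gamma: 0.034657359     # provenance: calibrated  (ln 2 / 20 h: 20 h mass doubling)
growth: exponential    # provenance: paper  (linear mode available as alternative)

# --- division asymmetry -----------------------------------------------
delta_mean: 0.5        # provenance: paper
delta_sd: 0.0167       # provenance: paper
delta_clip: 0.1        # provenance: calibrated  (delta clipped to (clip, 1-clip))

# --- noise ------------------------------------------------------------
threshold_noise_sd: 0.033   # provenance: paper  (G ~ Gaussian(mean 1, sd 3.3%))
noise_dna: 0.03             # provenance: paper
noise_cyclin: 0.15          # provenance: paper

# --- initial conditions -----------------------------------------------
init_cyca: 1           # provenance: paper
init_cycb: 1           # provenance: paper
init_cyce: 1           # provenance: paper
init_mass: 3           # provenance: paper
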