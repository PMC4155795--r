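## Frozen default rule parameters, one set per shipped cell type.
##
## The functional forms (order-inverse branching, small per-step
## termination probability, weighted cue composition) are fixed by the rule
## definitions; the numeric constants below were calibrated once against
## the published population medians for each cell type (motor, granule,
## L5 pyramidal) and are frozen here. Configs may override any field.
##
## Version tag bumped whenever a calibrated value changes.
PARAMS_VERSION <- "1.0"

#' Default growth-rule parameters for a shipped cell type
#'
#' @param cell_type "motor", "granule" or "pyramidal".
#' @return named list of rule parameters (see the methods vignette for the
#'   meaning, units and provenance of each field).
#' @export
default_params <- function(cell_type) {
  switch(cell_type,
    motor = list(
      n_stems = c(12L, 14L),
      step_length = 20,            # um per update
      branch_base = 0.145,         # branch prob = min(1, base / order)
      term_prob = 0.0095,
      branch_angle = 60,           # full bifurcation angle, degrees
      max_branch_order = Inf,
      w_heading = 3, w_soma = 1, soma_scale = 400,
      w_random = 1.3,
      initial_radius = 3, taper = 0.96, branch_taper = 0.85,
      min_radius = 0.3),
    granule = list(
      n_stems = c(2L, 2L),
      depth_axis = 2L,             # superficial surface at max y
      step_length = 10,
      branch_base = 0.78,          # with decay 2: branching is proximal
      branch_decay = 2,
      term_prob = 0.002,
      branch_angle = 55,
      stem_angle = 70,             # divergence of the two primary stems
      max_branch_order = Inf,
      w_heading = 1.5, w_self = 1.5, self_scale = 15,
      w_superficial = 2.2, w_random = 1.1,
      initial_radius = 1.2, taper = 0.97, branch_taper = 0.9,
      min_radius = 0.3),
    pyramidal = list(
      n_stems = c(5L, 7L),         # basal stems; always one apical stem
      initial_radius = 1.5,
      taper = 0.97, branch_taper = 0.9, min_radius = 0.3,
      step_length = 10,
      basal = list(
        step_length = 10,
        branch_base = 0.35,
        term_prob = 0.1,
        branch_angle = 60,
        max_branch_order = 6,      # no branching above order 6
        w_heading = 2.5, w_self = 1, self_scale = 15, w_random = 1.2),
      apical = list(
        step_length = 10,
        pia_stop = 35,             # hard termination distance to pia, um
        oblique_layers = c("L5", "L4"),
        oblique_sprout_prob = list(L5 = 0.08, L4 = 0.65),
        layer_branch_probs = list(L3 = 0.5, L2 = 0.115, L1 = 0.12),
        ## per-layer centrifugal-order budget; L3 hosts the near-certain
        ## main bifurcation of the trunk into the tuft
        max_order_per_layer = list(L3 = 2, L2 = 4, L1 = 2),
        term_prob_superficial = 0.012,
        branch_angle = 50,
        w_heading = 3, w_self = 1, self_scale = 15,
        w_pia = 2, pia_scale = 400, w_random = 1),
      oblique = list(
        step_length = 10,
        branch_prob = 0.01,        # flat per-step bifurcation probability
        term_prob = 0.035,
        branch_angle = 55,
        max_length = 300,          # path-length budget per oblique, um
        w_heading = 2, w_away = 1.5, w_up = 0.5, w_random = 1)),
    stop("config error: no default parameters for cell type '",
         cell_type, "'"))
}

## Parameter base for a rule entry ("pyramidal_soma" -> "pyramidal").
params_base_for <- function(rule_entry) {
  sub("_.*$", "", rule_entry)
}
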