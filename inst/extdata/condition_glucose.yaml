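# Batch growth condition: single limiting carbon source with the
# standard settings (initial biomass 0.003 gDW/L, 10 mmol/L source,
# time step 0.1 h). Metabolites listed under in_excess are never
# depleted; uptake_caps sets per-metabolite maximal uptake rates
# (mmol/gDW/h). Cap values are model-specific placeholders: adjust
# them to the uptake parameterization of the model in use.
condition_id: glucose
carbon_source: glc__D_e
initial_concentration: 10      # mmol/L
initial_biomass: 0.003         # gDW/L
time_step: 0.1                 # h
max_time: 100                  # h
mu_tol: 1.0e-6                 # 1/h
default_uptake_cap: 10         # mmol/gDW/h
in_excess:
  - o2_e
  - nh4_e
  - pi_e
  - so4_e
  - h2o_e
  - h_e
uptake_caps:
  glc__D_e: 10
  o2_e: 20
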