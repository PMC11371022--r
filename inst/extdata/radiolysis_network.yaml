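# Nine-species water-radiolysis / peroxyl-radical reaction network for the
# FLASH normal-tissue sparing model.
#
# Units: initial and resupply_conc in mol/L; g_value in umol/J (per Gy in
# unit-density tissue); rate_constant in 1/s (first order) or L/mol/s
# (second order). Pseudo-first-order constants absorb an implicit excess
# partner (cellular biomolecule pool, antioxidant pool, enzymes).
# Source tags: "radiolysis" = standard aqueous radiation-chemistry
# compilations (Buxton et al. critical review values); "cellular" =
# effective cellular/enzymatic scale chosen for this model (see the
# methods vignette).
species:
  - name: e_aq
    description: hydrated electron from water radiolysis
    initial: 0.0
    g_value: 0.28          # radiolysis: G ~ 2.7 / 100 eV
  - name: O2
    description: molecular oxygen, rediffusing from capillaries
    initial: 2.5e-6        # cellular: ~2 mmHg, low physiological oxygenation
    g_value: 0.0
    resupply_rate: 1.0     # cellular: rediffusion relaxation, 1/s
    resupply_conc: 2.5e-6
  - name: H2O2
    description: hydrogen peroxide
    initial: 0.0
    g_value: 0.073         # radiolysis: G ~ 0.7 / 100 eV
  - name: OH
    description: hydroxyl radical
    initial: 0.0
    g_value: 0.28          # radiolysis: G ~ 2.7 / 100 eV
  - name: H
    description: hydrogen atom
    initial: 0.0
    g_value: 0.062         # radiolysis: G ~ 0.6 / 100 eV
  - name: H2
    description: molecular hydrogen
    initial: 0.0
    g_value: 0.047         # radiolysis: G ~ 0.45 / 100 eV
  - name: O2m
    description: superoxide anion (HO2 lumped in at cellular pH)
    initial: 0.0
    g_value: 0.0
  - name: R
    description: carbon-centred biomolecule radical (RH + OH and direct effect)
    initial: 0.0
    g_value: 0.25          # cellular: direct-ionization yield of RH radicals
  - name: ROO
    description: peroxyl radical, the damage proxy (R + O2)
    initial: 0.0
    g_value: 0.0
reactions:
  - equation: "e_aq + O2 -> O2m"
    rate_constant: 1.9e10
    source: radiolysis
  - equation: "e_aq + H2O2 -> OH"
    rate_constant: 1.1e10
    source: radiolysis
  - equation: "e_aq + OH ->"
    rate_constant: 3.0e10
    source: radiolysis
  - equation: "2 e_aq -> H2"
    rate_constant: 5.5e9
    source: radiolysis
  - equation: "e_aq ->"
    rate_constant: 1.0e4
    source: cellular    # scavenging by cellular solutes
  - equation: "2 OH -> H2O2"
    rate_constant: 5.5e9
    source: radiolysis
  - equation: "OH + H2 -> H"
    rate_constant: 4.2e7
    source: radiolysis
  - equation: "OH + H2O2 -> O2m"
    rate_constant: 2.7e7
    source: radiolysis
  - equation: "OH -> R"
    rate_constant: 1.0e8
    source: cellular    # pseudo-first order: OH + RH biomolecule pool
  - equation: "H + O2 -> O2m"
    rate_constant: 2.1e10
    source: radiolysis
  - equation: "2 H -> H2"
    rate_constant: 7.8e9
    source: radiolysis
  - equation: "H + OH ->"
    rate_constant: 7.0e9
    source: radiolysis
  - equation: "R + O2 -> ROO"
    rate_constant: 4.9e9
    source: radiolysis  # diffusion-limited oxygen capture
  - equation: "2 R ->"
    rate_constant: 7.8e8
    source: radiolysis  # radical-radical recombination to inert R-R
  - equation: "R ->"
    rate_constant: 2.0e3
    source: cellular    # chemical repair of R by the thiol pool
  - equation: "2 ROO -> O2"
    rate_constant: 1.0e5
    source: cellular    # Russell-type bimolecular termination
  - equation: "ROO ->"
    rate_constant: 0.3
    source: cellular    # pseudo-first order: antioxidant / lipid targets
  - equation: "2 O2m -> H2O2 + O2"
    rate_constant: 2.0e5
    source: radiolysis  # dismutation near neutral pH
  - equation: "O2m ->"
    rate_constant: 10.0
    source: cellular    # superoxide dismutase, pseudo-first order
  - equation: "H2O2 ->"
    rate_constant: 1.0
    source: cellular    # catalase / peroxidase clearance
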