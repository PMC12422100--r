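# Default reaction catalogue for the four-species cellulolytic community.
# Cellulose is represented as glucose-equivalent (anhydroglucose, 162 g/mol);
# hydrolysis itself is not a fitted reaction. Water and protons are implicit
# (the pH-7 transformed-energy convention absorbs them), so carbon and
# electron balances are checked over the explicit CHO species only.
# gamma = degree of reduction (electron equivalents released on full
# oxidation to CO2/H2O) = 4*C + H - 2*O for CHO compounds.
# All values are user-editable; stoichiometries are per mol glucose-equivalent
# for the Ruminiclostridium cellulolyticum (Rc) reactions.
y_atp: 10.5            # g dry biomass per mol ATP (optional biomass coupling)
metabolites:
  glucose:  {formula: C6H12O6, phase: aqueous, carbon: 6, gamma: 24}
  lactate:  {formula: C3H6O3,  phase: aqueous, carbon: 3, gamma: 12}
  acetate:  {formula: C2H4O2,  phase: aqueous, carbon: 2, gamma: 8}
  ethanol:  {formula: C2H6O,   phase: aqueous, carbon: 2, gamma: 12}
  H2:       {formula: H2,      phase: gas,     carbon: 0, gamma: 2}
  CO2:      {formula: CO2,     phase: gas,     carbon: 1, gamma: 0}
  CH4:      {formula: CH4,     phase: gas,     carbon: 1, gamma: 8}
  biomass:  {formula: ~,       phase: biomass, carbon: 0, gamma: 0}
species:
  Rc: Ruminiclostridium cellulolyticum (cellulolytic fermenter)
  Mc: Methanosaeta concilii (acetoclastic methanogen)
  Mh: Methanospirillum hungatei (hydrogenotrophic methanogen)
  Dv: Desulfovibrio vulgaris (syntrophic lactate oxidizer, no sulfate)
reactions:
  lactate_fermentation:
    species: Rc
    stoich: {glucose: -1, lactate: 2}
    atp_yield: 2
    dg0_prime: -198
  hydrogenic_acetogenesis:
    species: Rc
    stoich: {glucose: -1, acetate: 2, CO2: 2, H2: 4}
    atp_yield: 4
    dg0_prime: -206
  mixed_acid_fermentation:
    species: Rc
    stoich: {glucose: -1, ethanol: 1, acetate: 1, CO2: 2, H2: 2}
    atp_yield: 3
    dg0_prime: -220
  hydrogenic_lactate_oxidation:
    species: Dv
    stoich: {lactate: -1, acetate: 1, CO2: 1, H2: 2}
    atp_yield: 1
    dg0_prime: -4.2
  hydrogenotrophic_methanogenesis:
    species: Mh
    stoich: {H2: -4, CO2: -1, CH4: 1}
    atp_yield: 0.5
    dg0_prime: -131
  acetoclastic_methanogenesis:
    species: Mc
    stoich: {acetate: -1, CH4: 1, CO2: 1}
    atp_yield: 0.25
    dg0_prime: -36
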