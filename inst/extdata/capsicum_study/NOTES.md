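# Bundled example study: sweet pepper on gold-mining-impacted soils

A screen-house study of *Capsicum annuum* grown on three soils sampled at
0.6, 3 and 10 km from artisanal gold-mining activity (San Martin de Loba,
Bolivar, Colombia). Concentrations are means over replicates, mg kg^-1 dry
weight.

Provenance of each table:

- `soils.csv` — total Hg/Pb/As per site before cultivation ("initial") plus
  the post-harvest Pb total for S1 ("final"). `sd` is the reported
  replicate standard deviation.
- `fractions.csv` — sequential-extraction percentages. The Pb rows (Tessier
  scheme: exchangeable F1, carbonate F2) are measured values. The Hg
  (Bloom scheme) and As rows are SYNTHETIC stand-ins: the study reports
  only that the bioavailable Hg and As fractions summed to below 1% at
  every site, so representative sub-1% values are encoded here to carry
  that classification through the pipeline.
- `tissues.csv` — root concentrations per site. The S3 Pb root was below
  the 0.08 mg kg^-1 plant detection limit and is stored censored. One row
  per site (site means); plant_id is nominal.
- `fruits.csv` — four harvests from the two fruit-producing sites. Pb and
  As entries below their plant detection limits (0.08 and 0.05 mg kg^-1)
  are censored; the single quantified Pb value is harvest C1 at S2.
- `crm.csv` — certified reference material (IAEA-336, trace elements in
  lichen) certified vs measured concentrations, ug g^-1.
- `config.json` — exposure scenario and toxicological/regulatory reference
  values with authority provenance.
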