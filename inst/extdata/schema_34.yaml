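- name: TST
  label: Time since transition to organic farming
  level: farm_description
  kind: continuous
  unit: year
  region_standardized: no
  range:
  - 0.0
  - 26.0
- name: Size
  label: Farm size
  level: farm_description
  kind: continuous
  unit: ha
  region_standardized: no
  range:
  - 11.0
  - 700.0
- name: LHI
  label: Landscape heterogeneity index, 1 km radius
  level: landscape
  kind: index
  unit: ''
  region_standardized: no
  range:
  - -4.0
  - 4.0
- name: Leys
  label: Proportion of rotational leys
  level: farm_management
  kind: percentage
  unit: '%'
  region_standardized: no
  range:
  - 0.0
  - 87.0
- name: Grains
  label: Proportion of cereal crops
  level: farm_management
  kind: percentage
  unit: '%'
  region_standardized: no
  range:
  - 6.0
  - 95.0
- name: Ocrops
  label: Proportion of other crops
  level: farm_management
  kind: percentage
  unit: '%'
  region_standardized: no
  range:
  - 0.0
  - 56.0
- name: PP
  label: Presence of pasture
  level: farm_management
  kind: dummy
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 1.0
- name: OFert_area
  label: Area with organic fertilizers
  level: farm_management
  kind: continuous
  unit: ha
  region_standardized: no
  range:
  - 0.0
  - 380.0
- name: AOFert
  label: Amount of organic fertilizers
  level: farm_management
  kind: continuous
  unit: t/ha
  region_standardized: no
  range:
  - 0.0
  - 70.0
- name: LDI
  label: Livestock density index
  level: farm_management
  kind: index
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 3.3
- name: SRM
  label: Straw and residue management (farm)
  level: farm_management
  kind: ordinal
  unit: ''
  region_standardized: no
  range:
  - 1.0
  - 3.0
- name: Freq_OFe
  label: Frequency of organic fertilizer application
  level: field_history
  kind: continuous
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 1.0
- name: OFe_AT
  label: Organic fertilizer application technique 2009-2011
  level: field_history
  kind: ordinal
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 2.0
- name: Min_N
  label: Mineral N on average 2009-2011
  level: field_history
  kind: continuous
  unit: kg/ha
  region_standardized: no
  range:
  - 0.0
  - 175.0
- name: Min_PK
  label: Mineral PK applied
  level: field_history
  kind: dummy
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 1.0
- name: PEST
  label: Pesticide application 2009-2011
  level: field_history
  kind: dummy
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 1.0
- name: STR_M
  label: Straw and residue management (field) 2009-2011
  level: field_history
  kind: ordinal
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 2.0
- name: Org_N12
  label: Nitrogen amount from organic fertilizers 2012
  level: field_current
  kind: continuous
  unit: kg/ha
  region_standardized: no
  range:
  - 0.0
  - 167.0
- name: OFe_AT12
  label: Organic fertilizer application technique 2012
  level: field_current
  kind: ordinal
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 2.0
- name: Min_N12
  label: Mineral N application 2012
  level: field_current
  kind: continuous
  unit: kg/ha
  region_standardized: no
  range:
  - 0.0
  - 175.0
- name: SMR_L12
  label: Straw and residues left before sowing 2012
  level: field_current
  kind: dummy
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 1.0
- name: StdSd
  label: Sowing date, deviation from region median
  level: field_current
  kind: continuous
  unit: day
  region_standardized: yes
  range:
  - -40.0
  - 40.0
- name: Seed
  label: Seed rate sown
  level: field_current
  kind: continuous
  unit: m-2
  region_standardized: no
  range:
  - 100.0
  - 220.0
- name: PC_pea
  label: Pea as preceding crop
  level: field_current
  kind: dummy
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 1.0
- name: PC_leys
  label: Leys as preceding crop
  level: field_current
  kind: dummy
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 1.0
- name: PC_cereal
  label: Cereals as preceding crop
  level: field_current
  kind: dummy
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 1.0
- name: PEST_12
  label: Pesticide use 2012
  level: field_current
  kind: dummy
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 1.0
- name: US_12
  label: Barley undersown with grass/clover
  level: field_current
  kind: dummy
  unit: ''
  region_standardized: no
  range:
  - 0.0
  - 1.0
- name: Weed
  label: Percentage weed cover, mean of three assessments
  level: field_current
  kind: percentage
  unit: '%'
  region_standardized: no
  range:
  - 0.0
  - 40.0
- name: SMN1
  label: Soil mineral nitrogen before fertilisation
  level: soil
  kind: continuous
  unit: kg/ha
  region_standardized: no
  range:
  - 12.0
  - 57.0
- name: pH
  label: Soil pH
  level: soil
  kind: continuous
  unit: ''
  region_standardized: no
  range:
  - 5.6
  - 8.0
- name: Tot_C
  label: Total soil carbon
  level: soil
  kind: percentage
  unit: '%'
  region_standardized: no
  range:
  - 1.1
  - 12.0
- name: Tot_N
  label: Total soil nitrogen
  level: soil
  kind: percentage
  unit: '%'
  region_standardized: no
  range:
  - 0.1
  - 1.0
- name: Clay
  label: Soil clay content, deviation from region median
  level: soil
  kind: percentage
  unit: '%'
  region_standardized: yes
  range:
  - -50.0
  - 50.0
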