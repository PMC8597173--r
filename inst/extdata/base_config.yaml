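strategies:
  dexamethasone:
    id: dexamethasone
    drug_unit_cost: 1075.0
    administration_unit_cost: 90.0
    cycle_length_months: 5.0
    adverse_events:
    - name: IOP medication
      unit_cost: 77.549999999999997
      incidence_per_cycle: 0.089
      once_only: no
    - name: Laser
      unit_cost: 82.0
      incidence_per_cycle: 0.0049
      once_only: yes
    - name: Vitrectomy
      unit_cost: 1195.0
      incidence_per_cycle: 0.0047
      once_only: yes
    - name: Cataract
      unit_cost: 1373.0
      incidence_per_cycle: 0.0577
      once_only: yes
    - name: Endophthalmitis
      unit_cost: 3101.0
      incidence_per_cycle: 0.0025
      once_only: no
    - name: Retinal detachment
      unit_cost: 2706.0
      incidence_per_cycle: 0.0004
      once_only: no
  triamcinolone:
    id: triamcinolone
    drug_unit_cost: 207.0
    administration_unit_cost: 76.0
    cycle_length_months: 4.0
    adverse_events:
    - name: IOP medication
      unit_cost: 77.549999999999997
      incidence_per_cycle: 0.1228
      once_only: no
    - name: Laser
      unit_cost: 82.0
      incidence_per_cycle: 0.0065
      once_only: yes
    - name: Vitrectomy
      unit_cost: 1195.0
      incidence_per_cycle: 0.0129
      once_only: yes
    - name: Cataract
      unit_cost: 1373.0
      incidence_per_cycle: 0.1264
      once_only: yes
    - name: Endophthalmitis
      unit_cost: 3101.0
      incidence_per_cycle: 0.002
      once_only: no
    - name: Retinal detachment
      unit_cost: 2706.0
      incidence_per_cycle: 0.0003
      once_only: no
matrices:
  dexamethasone:
    early:
    - - 0.962989346963617
      - 0.029608522429106
      - 0.007402130607277
      - 0.0
      - 0.0
    - - 0.0
      - 0.969815172951469
      - 0.024147861638825
      - 0.006036965409706
      - 0.0
    - - 0.0
      - 0.083996030343969
      - 0.896836146491425
      - 0.015334258531686
      - 0.003833564632921
    - - 0.0
      - 0.017226022779431
      - 0.068904091117726
      - 0.899873424669626
      - 0.013996461433217
    - - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 1.0
    late:
    - - 0.962989346963617
      - 0.029608522429106
      - 0.007402130607277
      - 0.0
      - 0.0
    - - 0.0
      - 0.963866640900989
      - 0.028906687279209
      - 0.007226671819802
      - 0.0
    - - 0.0
      - 0.071396625792373
      - 0.905637503139859
      - 0.018372696854214
      - 0.004593174213554
    - - 0.0
      - 0.014642119362517
      - 0.058568477450067
      - 0.910012551404522
      - 0.016776851782894
    - - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 1.0
  triamcinolone:
    early:
    - - 0.970280238373079
      - 0.023775809301537
      - 0.005943952325384
      - 0.0
      - 0.0
    - - 0.0
      - 0.967803118626235
      - 0.025757505099012
      - 0.006439376274753
      - 0.0
    - - 0.0
      - 0.303996030343969
      - 0.675558359468551
      - 0.016356488149984
      - 0.004089122037496
    - - 0.0
      - 0.061226022779432
      - 0.244904091117726
      - 0.678940353544778
      - 0.014929532558065
    - - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 1.0
    late:
    - - 0.970280238373079
      - 0.023775809301537
      - 0.005943952325384
      - 0.0
      - 0.0
    - - 0.0
      - 0.967803118626235
      - 0.025757505099012
      - 0.006439376274753
      - 0.0
    - - 0.0
      - 0.258396625792373
      - 0.721157764020146
      - 0.016356488149984
      - 0.004089122037496
    - - 0.0
      - 0.052042119362517
      - 0.208168477450067
      - 0.724859870629351
      - 0.014929532558065
    - - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 1.0
followup:
- name: OCT + medical visit
  unit_cost: 115.0
  utilization_per_year: 6.0
- name: IOP measurement
  unit_cost: 76.0
  utilization_per_year: 13.0
- name: FAG
  unit_cost: 77.0
  utilization_per_year: 1.0
rehab:
  components:
  - name: Occupational rehabilitation
    annual_cost: 2496.0
  - name: Discretionary rehabilitation
    annual_cost: 2176.0
  - name: Medical rehabilitation
    annual_cost: 2648.0
  applies_to_states:
  - 4
  - 5
utilities:
  name: base
  utility_by_state:
  - 0.97
  - 0.89
  - 0.81
  - 0.55
  - 0.4
horizons_years:
- 2.0
- 5.0
discount_rates:
- 0.0
- 0.03
cohort_size: 1000.0
seed: 1
switches:
  state5_treatment: no
  followup_in_state5: no
  once_only_mode: saturating
  final_cycle: extend
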