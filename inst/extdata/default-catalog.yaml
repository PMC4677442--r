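items:
- id: 1
  label: Prior intracranial hemorrhage (any time)
  severity: exclusion
  extractable: yes
  provisional: no
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - intracranial hemorrhage
        - intracerebral hemorrhage
        - subarachnoid hemorrhage
        codes: []
      lookback_days: unlimited
- id: 2
  label: Serious head trauma within 3 months
  severity: exclusion
  extractable: yes
  provisional: yes
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - head trauma
        - traumatic brain injury
        - skull fracture
        codes: []
      lookback_days: 90.0
- id: 3
  label: Ischemic stroke within 3 months
  severity: exclusion
  extractable: yes
  provisional: no
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - ischemic stroke
        - stroke
        - cerebral infarction
        codes: []
      lookback_days: 90.0
- id: 4
  label: Major surgery within 14 days
  severity: exclusion
  extractable: yes
  provisional: yes
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - major surgery
        - surgical procedure
        codes: []
      lookback_days: 14.0
- id: 5
  label: Gastrointestinal or urinary tract hemorrhage within 21 days
  severity: exclusion
  extractable: yes
  provisional: yes
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - gastrointestinal hemorrhage
        - gi bleeding
        - urinary tract hemorrhage
        codes: []
      lookback_days: 21.0
- id: 6
  label: Arterial puncture at a noncompressible site within 7 days
  severity: exclusion
  extractable: yes
  provisional: yes
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - arterial puncture
        codes: []
      lookback_days: 7.0
- id: 7
  label: Lumbar puncture within 7 days
  severity: exclusion
  extractable: yes
  provisional: yes
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - lumbar puncture
        codes: []
      lookback_days: 7.0
- id: 8
  label: Acute myocardial infarction within 3 months
  severity: exclusion
  extractable: yes
  provisional: yes
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - myocardial infarction
        codes: []
      lookback_days: 90.0
- id: 9
  label: Acute pericarditis
  severity: exclusion
  extractable: yes
  provisional: yes
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - pericarditis
        codes: []
      lookback_days: 90.0
- id: 10
  label: Known intracranial neoplasm
  severity: exclusion
  extractable: yes
  provisional: yes
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - intracranial neoplasm
        - brain tumor
        codes: []
      lookback_days: unlimited
- id: 11
  label: Known cerebral arteriovenous malformation
  severity: exclusion
  extractable: yes
  provisional: yes
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - arteriovenous malformation
        codes: []
      lookback_days: unlimited
- id: 12
  label: Known intracranial aneurysm
  severity: exclusion
  extractable: yes
  provisional: yes
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - intracranial aneurysm
        codes: []
      lookback_days: unlimited
- id: 13
  label: Significant liver disease
  severity: exclusion
  extractable: yes
  provisional: no
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - liver cirrhosis
        - cirrhosis
        - hepatic failure
        - severe liver disease
        codes: []
      lookback_days: unlimited
- id: 14
  label: Known bleeding diathesis or hemorrhagic disorder
  severity: exclusion
  extractable: yes
  provisional: yes
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - bleeding diathesis
        - hemophilia
        - hemorrhagic disorder
        codes: []
      lookback_days: unlimited
- id: 15
  label: Severe renal disease (hemodialysis)
  severity: exclusion
  extractable: yes
  provisional: no
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - hemodialysis
        - end-stage renal disease
        codes: []
      lookback_days: unlimited
- id: 16
  label: Current oral anticoagulant use
  severity: exclusion
  extractable: yes
  provisional: no
  predicate:
    exists:
      source: medication
      concepts:
        labels:
        - warfarin
        - dabigatran
        - rivaroxaban
        - apixaban
        - anticoagulant
        codes: []
      lookback_days: 30.0
- id: 17
  label: Known history of both stroke and diabetes
  severity: exclusion
  extractable: yes
  provisional: no
  predicate:
    all:
    - exists:
        source: diagnosis
        concepts:
          labels:
          - ischemic stroke
          - stroke
          - cerebral infarction
          codes: []
        lookback_days: unlimited
    - exists:
        source: diagnosis
        concepts:
          labels:
          - diabetes
          - diabetes mellitus
          - type 2 diabetes
          codes: []
        lookback_days: unlimited
- id: 18
  label: Severe stroke (NIHSS > 25)
  severity: exclusion
  extractable: no
  provisional: yes
  on_site_note: NIHSS > 25 measured at presentation
- id: 19
  label: Platelet count <= 100,000/mm3
  severity: exclusion
  extractable: no
  provisional: yes
  on_site_note: platelet count from current labs
- id: 20
  label: Blood glucose < 50 or > 400 mg/dL
  severity: exclusion
  extractable: no
  provisional: yes
  on_site_note: point-of-care glucose
- id: 21
  label: Blood pressure > 185/110 mmHg refractory to treatment
  severity: exclusion
  extractable: no
  provisional: yes
  on_site_note: blood pressure at presentation
- id: 22
  label: Onset beyond the treatment time window
  severity: exclusion
  extractable: no
  provisional: yes
  on_site_note: onset-to-needle time
- id: 23
  label: Rapidly improving or minor symptoms
  severity: exclusion
  extractable: no
  provisional: yes
  on_site_note: serial neurological examination
- id: 24
  label: CT evidence of hemorrhage or extensive infarction
  severity: exclusion
  extractable: no
  provisional: yes
  on_site_note: current brain CT read
- id: 25
  label: Seizure at stroke onset with postictal impairment
  severity: exclusion
  extractable: no
  provisional: yes
  on_site_note: witnessed onset account
- id: 26
  label: Pregnancy
  severity: exclusion
  extractable: no
  provisional: yes
  on_site_note: pregnancy test / history at presentation
advisories:
- label: atrial fibrillation
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - atrial fibrillation
        codes: []
      lookback_days: unlimited
- label: dementia
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - dementia
        codes: []
      lookback_days: unlimited
- label: heart failure
  predicate:
    exists:
      source: diagnosis
      concepts:
        labels:
        - heart failure
        - congestive heart failure
        codes: []
      lookback_days: unlimited
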