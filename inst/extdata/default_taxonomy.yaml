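# Default curation taxonomy: the printed core of the IEDB triage tree.
# Production trees extend this with further Level-2/3 branches via user config.
categories:
  - name: Allergy
    priority: high
  - name: Autoimmunity
    priority: high
    children:
      - name: Beta-Amyloid
      - name: Diabetes
        children:
          - name: GAD
          - name: HSP
          - name: IA2
          - name: IGRP
          - name: INSULIN
          - name: OTH
            catch_all: true
          - name: VAR
            catch_all: true
      - name: General Autoimmune
      - name: Lupus
      - name: Multiple Sclerosis
      - name: Myasthenia Gravis
      - name: Rheumatoid Arthritis
  - name: Infectious Disease
    priority: high
  - name: Transplantation
    priority: high
    skip_level2: true
  - name: Cancer
    priority: low
    skip_level2: true
  - name: HIV
    priority: low
    max_level: 1
  - name: Other
    priority: low
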