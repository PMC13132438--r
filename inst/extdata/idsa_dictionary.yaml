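# Illustrative Spanish dictionary for the nine modified IDSA/ATS
# severity criteria. Patterns are regular expressions applied to
# normalised text (lowercased, diacritics folded). This is a synthetic,
# illustrative dictionary -- not any study's production lexicon.
#
# Each criterion: detection patterns, a score weight, and optional
# context rules (anchor + companion within a token distance) used by the
# V2 matcher to recover compound expressions. `plant` strings are surface
# forms the synthetic note generator embeds; every plant matches its own
# criterion's patterns (or, for context rules, the rule).
age_component:
  threshold: 65
  points: 1
criteria:
  invasive_ventilation:
    weight: 1
    patterns:
      - "ventilacion mecanica invasiva"
      - "ventilacion invasiva"
      - "intubacion orotraqueal"
      - "soporte ventilatorio invasivo"
    plant:
      - "requiere ventilacion mecanica invasiva"
      - "se realiza intubacion orotraqueal"
  septic_shock:
    weight: 1
    patterns:
      - "choque septico"
      - "shock septico"
      - "soporte vasopresor"
      - "norepinefrina en infusion"
    plant:
      - "cursa con choque septico"
      - "requiere soporte vasopresor"
  tachypnea:
    weight: 1
    patterns:
      - "taquipnea"
      - "polipnea"
      - "frecuencia respiratoria elevada"
    plant:
      - "presenta taquipnea marcada"
      - "se observa polipnea"
  pao2_fio2:
    weight: 1
    patterns:
      - "pafi menor de 250"
      - "pao2/fio2 menor de 250"
      - "hipoxemia severa"
    context_rules:
      - anchor: "pafi|pao2/fio2"
        companion: "\\b(1[0-9]{2}|2[0-4][0-9]|[1-9][0-9]?)\\b"
        max_distance: 4
        plant: "pafi de 230"
    plant:
      - "pao2/fio2 menor de 250"
      - "hipoxemia severa documentada"
  multilobar_opacities:
    weight: 1
    patterns:
      - "opacidades multilobares"
      - "infiltrados multilobares"
      - "compromiso multilobar"
    context_rules:
      - anchor: "opacidades|infiltrados"
        companion: "bilaterales|multilobares|varios lobulos"
        max_distance: 5
        plant: "infiltrados alveolares bilaterales"
    plant:
      - "radiografia con opacidades multilobares"
      - "compromiso multilobar extenso"
  confusion:
    weight: 1
    patterns:
      - "confusion"
      - "desorientacion"
      - "alteracion del estado de conciencia"
      - "estupor"
    plant:
      - "episodios de confusion"
      - "alteracion del estado de conciencia"
  uremia:
    weight: 1
    patterns:
      - "uremia"
      - "nitrogeno ureico elevado"
    context_rules:
      - anchor: "\\bbun\\b"
        companion: "\\b([2-9][0-9]|1[0-9]{2})\\b"
        max_distance: 3
        plant: "bun 45"
    plant:
      - "uremia en ascenso"
      - "nitrogeno ureico elevado"
  leukopenia:
    weight: 1
    patterns:
      - "leucopenia"
      - "leucocitos menor de 4000"
    plant:
      - "hemograma con leucopenia"
      - "leucocitos menor de 4000"
  hypotension:
    weight: 1
    patterns:
      - "hipotension"
      - "presion arterial baja"
    plant:
      - "hipotension que requiere liquidos"
      - "presion arterial baja persistente"
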