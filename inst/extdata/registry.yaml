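# Default disease-attribute registry.
#
# Four dimensions: chronic_pain, acute_event, chronic_disorder,
# treatment_complication. Acute events are instantaneous; subacute disorders
# can remit (claims rule: qualifying claim within the previous two years);
# chronic disorders are absorbing. The ICD-9/ICD-10 code lists below are
# ILLUSTRATIVE defaults (one or two plausible stem codes per attribute) and
# are intended to be overridden by a study-specific configuration; they are
# not a clinically validated code set.
scd_case_definition:
  include_icd9: ["2826", "28241", "28242"]
  include_icd10: ["D57", "D578"]
  exclude_icd9: ["2825"]
  exclude_icd10: ["D573"]

attributes:
  # ---- acute events (13, instantaneous) ----
  - {name: vaso_occlusive_pain, dimension: acute_event, persistence: instantaneous,
     icd9: ["28262", "28242"], icd10: ["D5700"], severity_marker: true}
  - {name: stroke, dimension: acute_event, persistence: instantaneous,
     icd9: ["434"], icd10: ["I63"], severity_marker: true}
  - {name: fever, dimension: acute_event, persistence: instantaneous,
     icd9: ["7806"], icd10: ["R509"], severity_marker: false}
  - {name: splenic_disease, dimension: acute_event, persistence: instantaneous,
     icd9: ["2892"], icd10: ["D735"], severity_marker: false}
  - {name: priapism, dimension: acute_event, persistence: instantaneous,
     icd9: ["60783"], icd10: ["N483"], severity_marker: false}
  - {name: dactylitis, dimension: acute_event, persistence: instantaneous,
     icd9: ["7368"], icd10: ["M6780"], severity_marker: false}
  - {name: acute_chest_syndrome, dimension: acute_event, persistence: instantaneous,
     icd9: ["5173"], icd10: ["D5701"], severity_marker: true}
  - {name: myocardial_infarction, dimension: acute_event, persistence: instantaneous,
     icd9: ["410"], icd10: ["I21"], severity_marker: false}
  - {name: infections, dimension: acute_event, persistence: instantaneous,
     icd9: ["486", "599"], icd10: ["J189", "N390"], severity_marker: false}
  - {name: acute_renal_failure, dimension: acute_event, persistence: instantaneous,
     icd9: ["5849"], icd10: ["N179"], severity_marker: false}
  - {name: multi_organ_failure, dimension: acute_event, persistence: instantaneous,
     icd9: ["78552"], icd10: ["R6521"], severity_marker: true}
  - {name: bacteremia_sepsis, dimension: acute_event, persistence: instantaneous,
     icd9: ["0389", "7907"], icd10: ["A419", "R7881"], severity_marker: false}
  - {name: acute_anemia, dimension: acute_event, persistence: instantaneous,
     icd9: ["2851"], icd10: ["D62"], severity_marker: false}

  # ---- subacute disorders (7, incl. chronic pain as its own dimension) ----
  - {name: chronic_pain, dimension: chronic_pain, persistence: subacute,
     icd9: ["33829"], icd10: ["G8929"], severity_marker: false}
  - {name: fatigue, dimension: chronic_disorder, persistence: subacute,
     icd9: ["78079"], icd10: ["R5383"], severity_marker: false}
  - {name: asthma, dimension: chronic_disorder, persistence: subacute,
     icd9: ["49390"], icd10: ["J45909"], severity_marker: false}
  - {name: leg_ulcers, dimension: chronic_disorder, persistence: subacute,
     icd9: ["7071"], icd10: ["L97909"], severity_marker: false}
  - {name: hepatobiliary_liver_disease, dimension: chronic_disorder, persistence: subacute,
     icd9: ["5749", "5718"], icd10: ["K808", "K769"], severity_marker: false}
  - {name: sleep_disordered_breathing, dimension: chronic_disorder, persistence: subacute,
     icd9: ["32723"], icd10: ["G4733"], severity_marker: false}
  - {name: depression_psychosis, dimension: chronic_disorder, persistence: subacute,
     icd9: ["311", "2989"], icd10: ["F329", "F29"], severity_marker: false}

  # ---- chronic disorders (6, absorbing) ----
  - {name: chronic_renal_disease, dimension: chronic_disorder, persistence: chronic,
     icd9: ["585"], icd10: ["N18"], severity_marker: false}
  - {name: pulmonary_hypertension_cvd, dimension: chronic_disorder, persistence: chronic,
     icd9: ["4160", "4280"], icd10: ["I270", "I509"], severity_marker: false}
  - {name: chronic_lung_disease, dimension: chronic_disorder, persistence: chronic,
     icd9: ["496"], icd10: ["J44"], severity_marker: false}
  - {name: ocular_complications, dimension: chronic_disorder, persistence: chronic,
     icd9: ["36229"], icd10: ["H3500"], severity_marker: false}
  - {name: cognitive_impairment, dimension: chronic_disorder, persistence: chronic,
     icd9: ["2948"], icd10: ["F068"], severity_marker: false}
  - {name: avascular_necrosis, dimension: chronic_disorder, persistence: chronic,
     icd9: ["73342"], icd10: ["M87"], severity_marker: false}

  # ---- treatment complications ----
  - {name: leukopenia, dimension: treatment_complication, persistence: subacute,
     icd9: ["2880"], icd10: ["D70"], severity_marker: false}
  - {name: thrombocytopenia, dimension: treatment_complication, persistence: subacute,
     icd9: ["2875"], icd10: ["D696"], severity_marker: false}
  - {name: oligospermia_azospermia, dimension: treatment_complication, persistence: chronic,
     icd9: ["6061"], icd10: ["N461"], severity_marker: false}
  - {name: iron_overload, dimension: treatment_complication, persistence: chronic,
     icd9: ["2750"], icd10: ["E83110"], severity_marker: false}
  - {name: transfusion_reaction, dimension: treatment_complication, persistence: subacute,
     icd9: ["9998"], icd10: ["T8092"], severity_marker: false}
  - {name: transfusion_infection, dimension: treatment_complication, persistence: subacute,
     icd9: ["99939"], icd10: ["T8022"], severity_marker: false}
  - {name: graft_versus_host_disease, dimension: treatment_complication, persistence: chronic,
     icd9: ["2795"], icd10: ["D8981"], severity_marker: false}
  - {name: graft_failure, dimension: treatment_complication, persistence: chronic,
     icd9: ["9968"], icd10: ["T8602"], severity_marker: false}
  - {name: bronchiolitis_obliterans, dimension: treatment_complication, persistence: chronic,
     icd9: ["4918"], icd10: ["J441"], severity_marker: false}
  - {name: osteoporosis, dimension: treatment_complication, persistence: chronic,
     icd9: ["73300"], icd10: ["M810"], severity_marker: false}
  - {name: posterior_reversible_encephalopathy, dimension: treatment_complication, persistence: subacute,
     icd9: ["3483"], icd10: ["I6783"], severity_marker: false}
  - {name: post_transplant_lymphoproliferative_disorder, dimension: treatment_complication, persistence: chronic,
     icd9: ["23877"], icd10: ["D4781"], severity_marker: false}
  - {name: secondary_malignancy, dimension: treatment_complication, persistence: chronic,
     icd9: ["1991"], icd10: ["C801"], severity_marker: false}

therapies:
  hydroxyurea: [leukopenia, thrombocytopenia, oligospermia_azospermia]
  transfusion: [iron_overload, transfusion_reaction, transfusion_infection]
  gene_therapy: [graft_failure, bronchiolitis_obliterans, osteoporosis,
                 iron_overload, depression_psychosis,
                 posterior_reversible_encephalopathy,
                 post_transplant_lymphoproliferative_disorder,
                 secondary_malignancy]
  hsct: [graft_versus_host_disease, graft_failure, bronchiolitis_obliterans,
         osteoporosis, iron_overload, depression_psychosis,
         posterior_reversible_encephalopathy,
         post_transplant_lymphoproliferative_disorder, secondary_malignancy]
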