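# WAG indicator-question schema: 5 welfare categories x 4 main questions,
# plus the two alternates used when a main question cannot be answered.
# `exclusive` marks a multi-select response that cannot co-occur with others
# (a "no findings" answer). Vocabularies for nut_fibre and wrk_age_started
# are package-defined: the source survey replaced both with their alternates
# throughout and did not publish their response lists.
multiselect_delimiter: ";"
questions:
  - id: nut_bcs
    prompt: "Body condition score"
    category: nutrition
    role: main
    multiselect: false
    levels:
      "Very thin/poor": bad
      "Thin/moderate": medium
      "Ideal": good
      "Fat": medium
      "Very fat": bad
  - id: nut_diet
    prompt: "Is the equid getting an appropriate diet?"
    category: nutrition
    role: main
    multiselect: true
    levels:
      "Pasture": good
      "Vitamins/minerals": good
      "Browse": good
      "Straw/stover": good
      "Chopped fibre/chaff": good
      "Hay": good
      "Haylage": good
      "Straights": medium
      "Creep feed": medium
      "Legumes/pulses": medium
      "Cereal grains": bad
      "Mix/muesli": bad
      "Silage": bad
  - id: nut_water_work
    prompt: "Access to clean water during working period"
    category: nutrition
    role: main
    multiselect: false
    levels:
      "Free access": good
      "Limited access": medium
      "No access": bad
  - id: nut_fibre
    prompt: "For how long is fibre available"
    category: nutrition
    role: main
    multiselect: false
    levels:
      "Constant access": good
      "Part of the day": medium
      "Rarely or never": bad
  - id: nut_water_housed
    prompt: "Presence of a clean water point (housed)"
    category: nutrition
    role: alternate
    alternate_for: nut_fibre
    multiselect: false
    levels:
      "Free access": good
      "Limited access": medium
      "No access": bad
  - id: hlt_lameness
    prompt: "Signs of lameness"
    category: health
    role: main
    multiselect: false
    levels:
      "No lameness": good
      "Lame but still moving": medium
      "Severely lame": bad
  - id: hlt_coat
    prompt: "Is the equid's coat healthy?"
    category: health
    role: main
    multiselect: false
    levels:
      "Yes": good
      "No": bad
  - id: hlt_skin
    prompt: "Skin alterations"
    category: health
    role: main
    multiselect: true
    exclusive: "No signs present"
    levels:
      "No signs present": good
      "Scars": medium
      "Alopecia": medium
      "Swellings": medium
      "Open wounds": bad
      "Sarcoids": bad
  - id: hlt_illness
    prompt: "Obvious signs of illness"
    category: health
    role: main
    multiselect: true
    exclusive: "No signs present"
    levels:
      "No signs present": good
      "Eye discharge": bad
      "Nasal discharge": bad
      "Signs of diarrhoea": bad
      "Discharge (penis or vulva)": bad
      "Abdominal pain": bad
  - id: beh_harmful
    prompt: "Harmful practices"
    category: behaviour
    role: main
    multiselect: true
    exclusive: "No"
    levels:
      "No": good
      "Limb tethering or hobbling": bad
      "Amputations or mutilations": bad
      "Firing and hot branding": bad
      "Rope noseband": bad
  - id: beh_attitude
    prompt: "General attitude of the equid at a distance"
    category: behaviour
    role: main
    multiselect: false
    levels:
      "At ease": good
      "Alert and active": good
      "Agitated, aggressive": bad
      "Apathetic, depressed, withdrawn": bad
  - id: beh_fear
    prompt: "Signs of fear and distress"
    category: behaviour
    role: main
    multiselect: true
    exclusive: "No signs of fear and distress present"
    levels:
      "No signs of fear and distress present": good
      "Head shyness": bad
      "Unpredictable or sudden movements": bad
      "Showing the whites of the eyes": bad
      "Sudden startle responses": bad
      "Aggressive behaviour": bad
      "Trembling": bad
  - id: beh_handler
    prompt: "Handlers interaction when holding the equid"
    category: behaviour
    role: main
    multiselect: false
    levels:
      "Relaxed and confident": good
      "Cautious/fearful": medium
      "Assertive/indifferent": medium
      "Aggressive": bad
  - id: wrk_hours
    prompt: "Number of working hours per day"
    category: working
    role: main
    multiselect: false
    levels:
      "Less than or equal to 3 h": good
      "More than 3, less than or equal to 6 h": good
      "More than 6, less than or equal to 9 h": medium
      "More than 9 h": bad
  - id: wrk_days
    prompt: "Number of days worked per week"
    category: working
    role: main
    multiselect: false
    levels:
      "5 days or less": good
      "6 days": medium
      "7 days": bad
  - id: wrk_rest
    prompt: "Does the equid have a rest break during the working day"
    category: working
    role: main
    multiselect: false
    levels:
      "Yes, equipment removed": good
      "Yes, equipment not removed": medium
      "No": bad
  - id: wrk_age_started
    prompt: "Age the equid started working"
    category: working
    role: main
    multiselect: false
    levels:
      "Over 3 years": good
      "2 to 3 years": medium
      "Under 2 years": bad
  - id: wrk_shade
    prompt: "Does the equid have access to shade during breaks"
    category: working
    role: alternate
    alternate_for: wrk_age_started
    multiselect: false
    levels:
      "Access to shade": good
      "Limited access to shade": medium
      "No access to shade": bad
  - id: hse_regime
    prompt: "Housing regime"
    category: housing
    role: main
    multiselect: false
    levels:
      "Stabled equid - access to field": good
      "Kept outside - access to shelter": good
      "Indoor housing": medium
      "Kept outside - no access to shelter": bad
  - id: hse_clean
    prompt: "Is the environment clean and free from hazards"
    category: housing
    role: main
    multiselect: false
    levels:
      "Yes": good
      "No": bad
  - id: hse_dimensions
    prompt: "Dimensions of the stable/shelter?"
    category: housing
    role: main
    multiselect: false
    levels:
      "Satisfactory": good
      "Not-Satisfactory": bad
  - id: hse_lying
    prompt: "Is there a clean, dry comfortable lying area"
    category: housing
    role: main
    multiselect: false
    levels:
      "Yes": good
      "No": bad
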