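[
  {
    "model_name": "3389",
    "n_contacts": 4,
    "contact_length": 1.5,
    "contact_pitch": 2.0,
    "tip_to_first_contact_centre": 2.25,
    "directional": false,
    "notes": "Medtronic 3389 with Activa PC; nominal datasheet geometry: 1.5 mm contacts, 0.5 mm spacing, 1.5 mm inactive tip."
  },
  {
    "model_name": "3387",
    "n_contacts": 4,
    "contact_length": 1.5,
    "contact_pitch": 3.0,
    "tip_to_first_contact_centre": 2.25,
    "directional": false,
    "notes": "Medtronic 3387; 1.5 mm contacts, 1.5 mm spacing."
  },
  {
    "model_name": "6147",
    "n_contacts": 4,
    "contact_length": 1.5,
    "contact_pitch": 3.0,
    "tip_to_first_contact_centre": 1.75,
    "directional": false,
    "notes": "Abbott/St Jude 6147 non-directional with Libra PC; nominal 1.5 mm contacts, 1.5 mm spacing, 1.0 mm tip."
  },
  {
    "model_name": "6170",
    "n_contacts": 4,
    "contact_length": 1.5,
    "contact_pitch": 2.0,
    "tip_to_first_contact_centre": 1.75,
    "directional": true,
    "notes": "Abbott/St Jude 6170 directional with Infinity; 1-3-3-1 segmented layout modelled as 4 ring levels; 1.5 mm contacts, 0.5 mm spacing."
  },
  {
    "model_name": "Cartesia",
    "n_contacts": 4,
    "contact_length": 1.5,
    "contact_pitch": 2.0,
    "tip_to_first_contact_centre": 1.75,
    "directional": true,
    "notes": "Boston Scientific Vercise Cartesia directional; 1-3-3-1 segmented layout modelled as 4 ring levels; 1.5 mm contacts, 0.5 mm spacing."
  }
]
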