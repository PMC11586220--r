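pt	hlgt	soc
Anxiety	Anxiety disorders and symptoms	Psychiatric disorders
Panic attack	Anxiety disorders and symptoms	Psychiatric disorders
Insomnia	Sleep disorders and disturbances	Psychiatric disorders
Abnormal dreams	Sleep disorders and disturbances	Psychiatric disorders
Middle insomnia	Sleep disorders and disturbances	Psychiatric disorders
Initial insomnia	Sleep disorders and disturbances	Psychiatric disorders
Somnambulism	Sleep disorders and disturbances	Psychiatric disorders
Depression	Depressive mood disorders and disturbances	Psychiatric disorders
Suicidal ideation	Suicidal and self-injurious behaviour	Psychiatric disorders
Headache	Headaches	Nervous system disorders
Migraine	Headaches	Nervous system disorders
Somnolence	Disturbances in consciousness	Nervous system disorders
Hypersomnia	Disturbances in consciousness	Nervous system disorders
Seizure	Seizures	Nervous system disorders
Sleep apnoea syndrome	Breathing abnormalities	Respiratory, thoracic and mediastinal disorders
Respiratory depression	Breathing abnormalities	Respiratory, thoracic and mediastinal disorders
Dyspnoea	Breathing abnormalities	Respiratory, thoracic and mediastinal disorders
Nausea	Nausea and vomiting symptoms	Gastrointestinal disorders
Vomiting	Nausea and vomiting symptoms	Gastrointestinal disorders
Diarrhoea	Gastrointestinal motility disorders	Gastrointestinal disorders
Constipation	Gastrointestinal motility disorders	Gastrointestinal disorders
Drug ineffective	Therapeutic and nontherapeutic responses	General disorders and administration site conditions
Condition aggravated	Therapeutic and nontherapeutic responses	General disorders and administration site conditions
Pyrexia	Body temperature conditions	General disorders and administration site conditions
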