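!site	COVID cases	lang=en
!category	Patients
!group	Demographics
Age	number	0:120		Age in years
Sex	enum	M|F
Home location	coordinates			Approximate home coordinates
!group	Clinical
Smoker	tristate			Current smoker
Main symptom	enum	fever|cough|anosmia|dyspnea|none		Main symptom at onset
Onset date	date	2020-01-01:2020-12-31		Date of symptom onset
Hospitalized	boolean
Comorbidities	text			Free-text comorbidity notes
Info page	url			External reference
!category	Samplings	connection=Has Patient->Patients
!group	Sampling
Sampling date	date	2020-01-01:2020-12-31
Temperature	number	30:45	°C	Body temperature at sampling
Result	enum	positive|negative|inconclusive		Swab outcome
Ct value	number	10:40		PCR cycle threshold
Home isolation	tristate			Isolating at home
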