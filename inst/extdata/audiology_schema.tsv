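!site	Audiological prostheses	lang=en
!category	Patients
!group	Demographics
Date of birth	date
Sex	enum	M|F
!category	Visits	connection=Has Patient->Patients
!group	Audiometry
Pure tone average of vocal gain during last control exam with intracochlear device on left ear	number	0:120	dB	Complex property with relational decomposition	measure=pure tone average; exam=last control; device=intracochlear; laterality=left
Pure tone average of vocal gain during last control exam with intracochlear device on right ear	number	0:120	dB		measure=pure tone average; exam=last control; device=intracochlear; laterality=right
Visit date	date
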