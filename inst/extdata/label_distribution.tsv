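type	count	provenance
Population	192	stated
OutcomeMeasures	190	stated
UnderpoweredStudy	185	stated
Generalization	72	interpolated
Blinding	65	interpolated
MissingData	60	interpolated
Intervention	55	interpolated
StudyDuration	55	interpolated
Randomization	50	interpolated
StatisticalAnalysis	50	interpolated
Control	45	interpolated
StudyDesign	40	interpolated
Other	15	interpolated
Setting	12	stated
Funding	4	stated
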