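name	level	parent	description
StudyDesign	top		Weaknesses tied to the trial design itself (crossover, factorial, cluster, and similar choices).
Population	top		Weaknesses in how trial participants were selected.
DiagnosticCriteria	fine	Population	Participants were included without standardized diagnostic criteria.
VerySpecificPopulation	fine	Population	Inclusion criteria were too narrow (single sex, athletes only, one education level or ethnicity).
ConvenienceSampling	fine	Population	Participants were recruited because they were easy to reach rather than representative.
Setting	top		Weaknesses related to where the trial was conducted.
Unicentric	fine	Setting	All participants came from a single centre.
Intervention	top		Weaknesses of the active treatment under study.
CompositeIntervention	fine	Intervention	Multimodal treatment made it impossible to isolate the effect of each component.
NonStandardTreatmentCharacteristics	fine	Intervention	Intervention parameters such as dosage or mode of delivery were not standardized.
Control	top		Weaknesses of the comparator or placebo condition.
NoPlaceboGroup	fine	Control	The trial had no control intervention.
ActivePlacebo	fine	Control	A non-inert intervention served as the comparator.
CareAsUsualControlGroup	fine	Control	The comparator was unstandardized usual care, so the contrast is ill-defined.
OutcomeMeasures	top		Weaknesses in the outcomes chosen or in how they were measured.
RelevantOutcomeExcluded	fine	OutcomeMeasures	Potentially informative outcomes were not collected.
PrecisionOfMeasurement	fine	OutcomeMeasures	Outcome measurement suffered from random error or low precision.
ValidityOfMeasurement	fine	OutcomeMeasures	The instrument was not validated for the studied population or construct (systematic error).
ResponsivenessOfMeasurement	fine	OutcomeMeasures	Measures were too coarse to detect real change when it occurred.
MissingData	top		Planned measurements were missing for some participants.
HighLossToFollowUp	fine	MissingData	Many participants left the trial before the planned end of follow-up.
UnbalancedDropout	fine	MissingData	Participants who dropped out differed systematically between arms (informative drop-out).
UnderpoweredStudy	top		Too few participants or outcome events to detect group differences.
SampleSize	fine	UnderpoweredStudy	The number of enrolled participants was insufficient, for instance due to recruitment problems.
Randomization	top		Weaknesses in the allocation of participants to arms.
UnbalancedGroups	fine	Randomization	Arms differed on prognostically important factors despite randomization.
PoorRandomizationMethods	fine	Randomization	Sequence generation, stratification or allocation concealment was suboptimal or absent.
Blinding	top		Weaknesses in masking participants or study personnel.
Patient	fine	Blinding	Participants were aware of their group assignment.
StudyTeam	fine	Blinding	Investigators, care providers, assessors or statisticians were not blinded.
StudyDuration	top		The experimental or follow-up period was too short or too long.
ExperimentPhaseDuration	fine	StudyDuration	The intervention phase was too short, possibly because of early stopping.
FollowUpDuration	fine	StudyDuration	Only short-term effects were assessed; long-term effects remain unknown.
StatisticalAnalysis	top		Weaknesses in the statistical methods applied.
MultipleTesting	fine	StatisticalAnalysis	Several hypotheses were tested simultaneously without adjustment.
ConfoundingFactors	fine	StatisticalAnalysis	Analyses were not adjusted for relevant covariates.
Funding	top		Limited or absent funding affected study conduct or completion.
Generalization	top		Results may not transfer beyond the specific setting, population, intervention or instruments used.
Other	top		Catch-all for limitation types that fit no other category.
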