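# Example age-related hospitalization code list (synthetic stand-in).
# The analysis expects a user-supplied list of ICD-10 categories for the
# 23 non-fatal age-related diseases screened from the broader set of
# aging-related conditions; this file ships a plausible example of 23
# common age-related 3-character categories so that the demo pipeline and
# the synthetic cohort generator can run end-to-end. Replace it with the
# study-specific list for real analyses.
# One code or range per line; '#' starts a comment.
I21   # acute myocardial infarction
I25   # chronic ischaemic heart disease
I48   # atrial fibrillation and flutter
I50   # heart failure
I63   # cerebral infarction
I64   # stroke, not specified
I67   # other cerebrovascular diseases
I70   # atherosclerosis
J18   # pneumonia, organism unspecified
J44   # chronic obstructive pulmonary disease
E11   # type 2 diabetes mellitus
N18   # chronic kidney disease
K57   # diverticular disease of intestine
M16   # osteoarthritis of hip
M17   # osteoarthritis of knee
M19   # other arthrosis
M81   # osteoporosis without pathological fracture
G20   # Parkinson disease
G30   # Alzheimer disease
F03   # unspecified dementia
H25   # senile cataract
H35   # retinal disorders incl. macular degeneration
H91   # hearing loss
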