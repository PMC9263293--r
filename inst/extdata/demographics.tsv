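subject_id	group	age	sex	field	tc_months
TC01	TC	24	F	Economics	18
TC02	TC	23	F	Economics	6
TC03	TC	22	M	Engineering	6
TC04	TC	20	M	Engineering	6
TC05	TC	20	M	Engineering	6
TC06	TC	20	M	Philosophy	6
TC07	TC	21	M	Science	6
TC08	TC	21	M	Science	6
TC09	TC	21	M	Science	6
TC10	TC	23	M	Literature	6
TC11	TC	21	M	Literature	6
TC12	TC	21	F	Management	6
TC13	TC	23	M	Management	6
TC14	TC	22	M	Management	6
TC15	TC	21	M	Engineering	18
TC16	TC	22	M	Engineering	18
TC17	TC	20	M	Engineering	18
TC18	TC	22	M	Law	6
TC19	TC	22	M	Law	6
TC20	TC	21	F	Philosophy	6
TC21	TC	20	F	Philosophy	6
TC22	TC	20	F	Philosophy	6
TC23	TC	20	F	Education	6
TC24	TC	20	F	Education	6
TC25	TC	20	M	Education	6
CT01	control	21	M	Engineering	0
CT02	control	21	M	Engineering	0
CT03	control	21	M	Engineering	0
CT04	control	21	M	Engineering	0
CT05	control	22	F	Engineering	0
CT06	control	23	M	Education	0
CT07	control	22	M	Arts	0
CT08	control	22	F	Arts	0
CT09	control	22	M	Arts	0
CT10	control	22	M	Law	0
CT11	control	22	M	Law	0
CT12	control	22	M	Law	0
CT13	control	21	F	Law	0
CT14	control	21	M	Management	0
CT15	control	22	M	Management	0
CT16	control	21	M	Management	0
CT17	control	22	M	Management	0
CT18	control	21	M	Science	0
CT19	control	21	M	Agriculture	0
CT20	control	22	M	Agriculture	0
CT21	control	21	M	Philosophy	0
CT22	control	22	M	Literature	0
CT23	control	22	F	Literature	0
CT24	control	22	F	Literature	0
CT25	control	21	F	Literature	0
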