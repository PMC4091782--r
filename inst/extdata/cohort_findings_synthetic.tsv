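sample_id	gene	evidence
SYN-T001	STAG2	truncating_mutation
SYN-T002	STAG2	truncating_mutation
SYN-T003	STAG2	truncating_mutation
SYN-T004	STAG2	truncating_mutation
SYN-T005	STAG2	truncating_mutation
SYN-T006	STAG2	truncating_mutation
SYN-T007	STAG2	truncating_mutation
SYN-T008	STAG2	truncating_mutation
SYN-T009	STAG2	truncating_mutation
SYN-T010	STAG2	truncating_mutation
SYN-T011	STAG2	truncating_mutation
SYN-T012	STAG2	truncating_mutation
SYN-T013	STAG2	truncating_mutation
SYN-T014	STAG2	truncating_mutation
SYN-T014	TP53	point_mutation
SYN-T015	TP53	point_mutation
SYN-T016	TP53	point_mutation
SYN-T017	TP53	point_mutation
SYN-T018	CDKN2A	homozygous_deletion
SYN-T019	CDKN2A	homozygous_deletion
SYN-T020	CDKN2A	homozygous_deletion
SYN-T021	CDKN2A	homozygous_deletion
SYN-T022	CDKN2A	homozygous_deletion
SYN-T023	CDKN2A	homozygous_deletion
SYN-T024	CDKN2A	homozygous_deletion
SYN-T025	CDKN2A	homozygous_deletion
SYN-T026	CDKN2A	homozygous_deletion
SYN-C001	STAG2	truncating_mutation
SYN-C002	STAG2	truncating_mutation
SYN-C003	STAG2	truncating_mutation
SYN-C004	STAG2	truncating_mutation
SYN-C005	STAG2	truncating_mutation
SYN-C006	STAG2	truncating_mutation
SYN-C007	STAG2	truncating_mutation
SYN-C008	STAG2	truncating_mutation
SYN-C009	STAG2	truncating_mutation
SYN-C010	STAG2	truncating_mutation
SYN-C011	STAG2	truncating_mutation
SYN-C012	STAG2	truncating_mutation
SYN-C013	STAG2	truncating_mutation
SYN-C014	STAG2	truncating_mutation
SYN-C015	STAG2	truncating_mutation
SYN-C016	STAG2	truncating_mutation
SYN-C005	TP53	point_mutation
SYN-C006	TP53	point_mutation
SYN-C007	TP53	point_mutation
SYN-C008	TP53	point_mutation
SYN-C009	TP53	point_mutation
SYN-C010	TP53	point_mutation
SYN-C011	TP53	point_mutation
SYN-C012	TP53	point_mutation
SYN-C013	TP53	point_mutation
SYN-C014	TP53	point_mutation
SYN-C015	TP53	point_mutation
SYN-C016	TP53	point_mutation
SYN-C017	TP53	point_mutation
SYN-C018	TP53	point_mutation
SYN-C019	TP53	point_mutation
SYN-C020	TP53	point_mutation
SYN-C021	TP53	point_mutation
SYN-C022	TP53	point_mutation
SYN-C023	TP53	point_mutation
SYN-C024	TP53	point_mutation
SYN-C025	TP53	point_mutation
SYN-C026	TP53	point_mutation
SYN-C027	TP53	point_mutation
SYN-C016	CDKN2A	homozygous_deletion
SYN-C017	CDKN2A	homozygous_deletion
SYN-C018	CDKN2A	homozygous_deletion
SYN-C019	CDKN2A	homozygous_deletion
SYN-C020	CDKN2A	homozygous_deletion
SYN-C021	CDKN2A	homozygous_deletion
SYN-C022	CDKN2A	homozygous_deletion
SYN-C023	CDKN2A	homozygous_deletion
SYN-C024	CDKN2A	homozygous_deletion
SYN-C025	CDKN2A	homozygous_deletion
SYN-C026	CDKN2A	homozygous_deletion
SYN-C027	CDKN2A	homozygous_deletion
SYN-C028	CDKN2A	homozygous_deletion
SYN-C029	CDKN2A	homozygous_deletion
SYN-C030	CDKN2A	homozygous_deletion
SYN-C031	CDKN2A	homozygous_deletion
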