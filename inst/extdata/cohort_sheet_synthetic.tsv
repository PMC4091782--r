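sample_id	class	fusion_positive	assays
SYN-T001	tumor	TRUE	NA
SYN-T002	tumor	TRUE	NA
SYN-T003	tumor	TRUE	NA
SYN-T004	tumor	TRUE	NA
SYN-T005	tumor	TRUE	NA
SYN-T006	tumor	TRUE	NA
SYN-T007	tumor	TRUE	NA
SYN-T008	tumor	TRUE	NA
SYN-T009	tumor	TRUE	NA
SYN-T010	tumor	TRUE	NA
SYN-T011	tumor	TRUE	NA
SYN-T012	tumor	TRUE	NA
SYN-T013	tumor	TRUE	NA
SYN-T014	tumor	TRUE	NA
SYN-T015	tumor	TRUE	NA
SYN-T016	tumor	TRUE	NA
SYN-T017	tumor	TRUE	NA
SYN-T018	tumor	TRUE	NA
SYN-T019	tumor	TRUE	NA
SYN-T020	tumor	TRUE	NA
SYN-T021	tumor	TRUE	NA
SYN-T022	tumor	TRUE	NA
SYN-T023	tumor	TRUE	NA
SYN-T024	tumor	TRUE	NA
SYN-T025	tumor	TRUE	NA
SYN-T026	tumor	TRUE	NA
SYN-T027	tumor	TRUE	NA
SYN-T028	tumor	TRUE	NA
SYN-T029	tumor	TRUE	NA
SYN-T030	tumor	TRUE	NA
SYN-T031	tumor	TRUE	NA
SYN-T032	tumor	TRUE	NA
SYN-T033	tumor	TRUE	NA
SYN-T034	tumor	TRUE	NA
SYN-T035	tumor	TRUE	NA
SYN-T036	tumor	TRUE	NA
SYN-T037	tumor	TRUE	NA
SYN-T038	tumor	TRUE	NA
SYN-T039	tumor	TRUE	NA
SYN-T040	tumor	TRUE	NA
SYN-T041	tumor	TRUE	NA
SYN-T042	tumor	TRUE	NA
SYN-T043	tumor	TRUE	NA
SYN-T044	tumor	TRUE	NA
SYN-T045	tumor	TRUE	NA
SYN-T046	tumor	TRUE	NA
SYN-T047	tumor	TRUE	NA
SYN-T048	tumor	TRUE	NA
SYN-T049	tumor	TRUE	NA
SYN-T050	tumor	TRUE	NA
SYN-T051	tumor	TRUE	NA
SYN-T052	tumor	TRUE	NA
SYN-T053	tumor	TRUE	NA
SYN-T054	tumor	TRUE	NA
SYN-T055	tumor	TRUE	NA
SYN-T056	tumor	TRUE	NA
SYN-T057	tumor	TRUE	NA
SYN-T058	tumor	TRUE	NA
SYN-T059	tumor	TRUE	NA
SYN-T060	tumor	TRUE	NA
SYN-T061	tumor	TRUE	NA
SYN-T062	tumor	TRUE	NA
SYN-T063	tumor	TRUE	NA
SYN-T064	tumor	TRUE	NA
SYN-T065	tumor	TRUE	NA
SYN-C001	cell_line	TRUE	NA
SYN-C002	cell_line	TRUE	NA
SYN-C003	cell_line	TRUE	NA
SYN-C004	cell_line	TRUE	NA
SYN-C005	cell_line	TRUE	NA
SYN-C006	cell_line	TRUE	NA
SYN-C007	cell_line	TRUE	NA
SYN-C008	cell_line	TRUE	NA
SYN-C009	cell_line	TRUE	NA
SYN-C010	cell_line	TRUE	NA
SYN-C011	cell_line	TRUE	NA
SYN-C012	cell_line	TRUE	NA
SYN-C013	cell_line	TRUE	NA
SYN-C014	cell_line	TRUE	NA
SYN-C015	cell_line	TRUE	NA
SYN-C016	cell_line	TRUE	NA
SYN-C017	cell_line	TRUE	NA
SYN-C018	cell_line	TRUE	NA
SYN-C019	cell_line	TRUE	NA
SYN-C020	cell_line	TRUE	NA
SYN-C021	cell_line	TRUE	NA
SYN-C022	cell_line	TRUE	NA
SYN-C023	cell_line	TRUE	NA
SYN-C024	cell_line	TRUE	NA
SYN-C025	cell_line	TRUE	NA
SYN-C026	cell_line	TRUE	NA
SYN-C027	cell_line	TRUE	NA
SYN-C028	cell_line	TRUE	NA
SYN-C029	cell_line	TRUE	NA
SYN-C030	cell_line	TRUE	NA
SYN-C031	cell_line	TRUE	NA
SYN-C032	cell_line	TRUE	NA
SYN-C033	cell_line	TRUE	STAG2
SYN-C034	cell_line	TRUE	STAG2
SYN-C035	cell_line	TRUE	STAG2
SYN-C036	cell_line	TRUE	STAG2
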