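gene	direction
300001	up
300002	up
300003	up
300004	up
300005	up
300006	up
300007	up
300008	up
300009	up
300010	up
300011	up
300012	up
300013	up
300014	up
300015	up
300016	up
300017	up
300018	up
300019	up
300020	up
300021	up
300022	up
300023	up
300024	up
300025	up
300026	up
300027	up
300028	up
300029	up
300030	up
300031	up
300032	up
300033	up
300034	up
300035	up
300036	up
300037	up
300038	up
300039	up
300040	up
300041	up
300042	up
300043	up
300044	up
300045	up
300046	up
300047	up
300048	up
300049	up
300050	up
300051	up
400001	down
400002	down
400003	down
400004	down
400005	down
400006	down
400007	down
400008	down
400009	down
400010	down
400011	down
400012	down
400013	down
400014	down
400015	down
400016	down
400017	down
400018	down
400019	down
400020	down
400021	down
400022	down
400023	down
400024	down
400025	down
400026	down
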