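gene	direction
100001	up
100002	up
100003	up
100004	up
100005	up
100006	up
100007	up
100008	up
100009	up
100010	up
100011	up
100012	up
100013	up
100014	up
100015	up
100016	up
100017	up
100018	up
100019	up
100020	up
100021	up
100022	up
100023	up
100024	up
100025	up
100026	up
100027	up
100028	up
100029	up
100030	up
100031	up
100032	up
100033	up
100034	up
200001	down
200002	down
200003	down
200004	down
200005	down
200006	down
200007	down
200008	down
200009	down
200010	down
200011	down
200012	down
200013	down
200014	down
200015	down
200016	down
200017	down
200018	down
200019	down
200020	down
200021	down
200022	down
200023	down
200024	down
200025	down
200026	down
200027	down
200028	down
200029	down
200030	down
200031	down
200032	down
200033	down
200034	down
200035	down
200036	down
200037	down
200038	down
200039	down
200040	down
200041	down
200042	down
200043	down
200044	down
200045	down
200046	down
200047	down
200048	down
200049	down
200050	down
200051	down
200052	down
200053	down
200054	down
200055	down
200056	down
200057	down
200058	down
200059	down
200060	down
200061	down
200062	down
200063	down
200064	down
200065	down
200066	down
200067	down
200068	down
200069	down
200070	down
200071	down
200072	down
200073	down
200074	down
200075	down
200076	down
200077	down
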