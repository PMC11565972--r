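residue	atom	class	mean	sd
A	CA	alpha	55.2	1.2
A	CA	coil	53.2	1
A	CA	beta	51.2	1.2
A	CA	positive_phi	53.3	NA
A	CB	alpha	18	0.9
A	CB	coil	18.7	1
A	CB	beta	21.2	1
A	CB	positive_phi	16	NA
A	CO	alpha	179.4	1.3
A	CO	coil	177.8	1.2
A	CO	beta	176.1	1.4
A	CO	positive_phi	178.2	NA
G	CA	alpha	46.9	1
G	CA	coil	44.9	1
G	CA	beta	43.9	1.2
G	CA	positive_phi	45.2	NA
G	CO	alpha	177.2	1.2
G	CO	coil	174.2	1.2
G	CO	beta	171.8	1.5
G	CO	positive_phi	174.8	NA
L	CA	alpha	57	1
L	CA	coil	54.6	1
L	CA	beta	52.9	1.3
L	CA	positive_phi	53.7	NA
L	CB	alpha	41.3	0.9
L	CB	coil	41.9	1
L	CB	beta	43.7	1.6
L	CB	positive_phi	39.2	NA
L	CO	alpha	178.5	1.2
L	CO	coil	177.1	1.2
L	CO	beta	175.7	1.4
L	CO	positive_phi	177.4	NA
S	CA	alpha	61	1.2
S	CA	coil	58.3	1.1
S	CA	beta	56.8	1.3
S	CA	positive_phi	58.4	NA
S	CB	alpha	62.9	1
S	CB	coil	63.8	1
S	CB	beta	65.2	1.3
S	CB	positive_phi	61.8	NA
T	CA	alpha	65.1	1.3
T	CA	coil	61.8	1.2
T	CA	beta	60.7	1.4
T	CA	positive_phi	61.9	NA
T	CB	alpha	68.2	1
T	CB	coil	69.8	1.1
T	CB	beta	71.2	1.4
T	CB	positive_phi	67.8	NA
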