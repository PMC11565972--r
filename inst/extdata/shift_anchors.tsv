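residue	atom	basin	shift
A	CA	alpha	55.3
A	CA	ppii_coil	53.25
A	CA	beta	51.3
A	CA	positive_phi	53.3
A	CB	alpha	18
A	CB	ppii_coil	18.6
A	CB	beta	21
A	CB	positive_phi	16
A	CO	alpha	179.4
A	CO	ppii_coil	177.8
A	CO	beta	176.1
A	CO	positive_phi	178.2
G	CA	alpha	46.7
G	CA	ppii_coil	44.7
G	CA	beta	42.8
G	CA	positive_phi	45.2
G	CO	alpha	176.3
G	CO	ppii_coil	174.2
G	CO	beta	172.1
G	CO	positive_phi	174.8
L	CA	alpha	56.9
L	CA	ppii_coil	54.5
L	CA	beta	52.4
L	CA	positive_phi	53.7
L	CB	alpha	41.2
L	CB	ppii_coil	41.6
L	CB	beta	42.7
L	CB	positive_phi	39.2
L	CO	alpha	178.5
L	CO	ppii_coil	177.1
L	CO	beta	175.7
L	CO	positive_phi	177.4
S	CA	alpha	60.8
S	CA	ppii_coil	58.3
S	CA	beta	56.6
S	CA	positive_phi	58.4
S	CB	alpha	62.9
S	CB	ppii_coil	63.8
S	CB	beta	65.3
S	CB	positive_phi	61.8
S	CO	alpha	176.8
S	CO	ppii_coil	174.6
S	CO	beta	173.5
S	CO	positive_phi	174.9
T	CA	alpha	65
T	CA	ppii_coil	61.8
T	CA	beta	60.6
T	CA	positive_phi	61.9
T	CB	alpha	68.2
T	CB	ppii_coil	69.8
T	CB	beta	71.2
T	CB	positive_phi	67.8
T	CO	alpha	175.9
T	CO	ppii_coil	174.5
T	CO	beta	173.2
T	CO	positive_phi	174.7
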