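{"format":"idpeaks-dihedral-library-1","basins":[{"residue":"A","basin":"alpha","phi0":-63,"psi0":-43,"sphi":11,"spsi":11,"weight":0.15},{"residue":"A","basin":"ppii_coil","phi0":-70,"psi0":145,"sphi":14,"spsi":16,"weight":0.62},{"residue":"A","basin":"beta","phi0":-130,"psi0":135,"sphi":18,"spsi":14,"weight":0.15},{"residue":"A","basin":"positive_phi","phi0":60,"psi0":45,"sphi":11,"spsi":11,"weight":0.08},{"residue":"L","basin":"alpha","phi0":-63,"psi0":-43,"sphi":11,"spsi":11,"weight":0.08},{"residue":"L","basin":"ppii_coil","phi0":-70,"psi0":145,"sphi":14,"spsi":16,"weight":0.64},{"residue":"L","basin":"beta","phi0":-130,"psi0":135,"sphi":18,"spsi":14,"weight":0.21},{"residue":"L","basin":"positive_phi","phi0":60,"psi0":45,"sphi":11,"spsi":11,"weight":0.07},{"residue":"G","basin":"alpha","phi0":-63,"psi0":-43,"sphi":11,"spsi":11,"weight":0.18},{"residue":"G","basin":"ppii_coil","phi0":-70,"psi0":145,"sphi":14,"spsi":16,"weight":0.49},{"residue":"G","basin":"beta","phi0":-130,"psi0":135,"sphi":18,"spsi":14,"weight":0.18},{"residue":"G","basin":"positive_phi","phi0":60,"psi0":45,"sphi":11,"spsi":11,"weight":0.15},{"residue":"S","basin":"alpha","phi0":-63,"psi0":-43,"sphi":11,"spsi":11,"weight":0.14},{"residue":"S","basin":"ppii_coil","phi0":-70,"psi0":145,"sphi":14,"spsi":16,"weight":0.6},{"residue":"S","basin":"beta","phi0":-130,"psi0":135,"sphi":18,"spsi":14,"weight":0.18},{"residue":"S","basin":"positive_phi","phi0":60,"psi0":45,"sphi":11,"spsi":11,"weight":0.08},{"residue":"T","basin":"alpha","phi0":-63,"psi0":-43,"sphi":11,"spsi":11,"weight":0.12},{"residue":"T","basin":"ppii_coil","phi0":-70,"psi0":145,"sphi":14,"spsi":16,"weight":0.58},{"residue":"T","basin":"beta","phi0":-130,"psi0":135,"sphi":18,"spsi":14,"weight":0.22},{"residue":"T","basin":"positive_phi","phi0":60,"psi0":45,"sphi":11,"spsi":11,"weight":0.08}]}
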