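# grindqsar probe/field parameters (flat key=value)
# Units: energies kcal/mol, distances Angstrom, charges elementary units.
# Lennard-Jones: E = eps*((rmin/r)^12 - 2*(rmin/r)^6), eps combined by
# geometric mean, rmin by sum of atom and probe radii.
# Electrostatics: 332.0636*qp*qa/(4*r^2)  (distance-dependent dielectric 4r)
# H-bond: Gaussian well -depth*exp(-(r-r0)^2/(2*sigma^2)) between a polar
# probe and complementary donor/acceptor atoms, directionally weighted.

clamp=5.0

# per-element Lennard-Jones well depth (kcal/mol) and minimum radius (A)
element.H.eps=0.02
element.H.rmin=1.20
element.C.eps=0.12
element.C.rmin=1.95
element.N.eps=0.16
element.N.rmin=1.80
element.O.eps=0.21
element.O.rmin=1.71
element.S.eps=0.25
element.S.rmin=2.00
element.P.eps=0.20
element.P.rmin=2.10
element.F.eps=0.08
element.F.rmin=1.60
element.Cl.eps=0.30
element.Cl.rmin=1.90
element.Br.eps=0.40
element.Br.rmin=2.00
element.I.eps=0.50
element.I.rmin=2.15

# DRY: hydrophobic probe. No charge, no H-bond term; its LJ attraction is
# enhanced on hydrophobic carbons and damped on polar atoms.
probe.DRY.charge=0.0
probe.DRY.eps=0.15
probe.DRY.rmin=1.70
probe.DRY.hb_role=none
probe.DRY.hydrophobic_scale=3.0
probe.DRY.polar_scale=0.5

# O: carbonyl-oxygen probe (H-bond acceptor); wells on donor atoms.
probe.O.charge=-0.35
probe.O.eps=0.20
probe.O.rmin=1.55
probe.O.hb_role=acceptor
probe.O.hb_depth=4.0
probe.O.hb_r0=2.9
probe.O.hb_sigma=0.4

# N1: amide-nitrogen probe (H-bond donor); wells on acceptor atoms.
probe.N1.charge=0.35
probe.N1.eps=0.18
probe.N1.rmin=1.60
probe.N1.hb_role=donor
probe.N1.hb_depth=4.0
probe.N1.hb_r0=2.9
probe.N1.hb_sigma=0.4

# TIP: shape probe; indicator shell (-1) of one grid spacing just outside
# the van der Waals surface.
probe.TIP.charge=0.0
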