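constant	value	unit	meaning
alpha	7.2973525693e-3	1	fine-structure constant
a0_cm	5.29177210903e-9	cm	Bohr radius
c_cm_s	2.99792458e10	cm/s	speed of light
hartree_eV	27.211386245988	eV	Hartree energy
au_debye	2.5417464519	D	atomic unit of electric dipole moment
t_au_s	2.4188843265857e-17	s	atomic unit of time
gm_cm4s	1e-50	cm^4 s/photon	one Goeppert-Mayer unit
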