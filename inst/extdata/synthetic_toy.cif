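# Synthetic example model for demonstrations and tests.
# This is NOT experimental data: a hand-made four-atom toy structure
# in P2(1)2(1)2(1) used to exercise the CIF reader, the kinematic
# structure-factor engine and the command-line tools.
data_SYNTHETIC_TOY
_cell_length_a 8.090(2)
_cell_length_b 9.940(2)
_cell_length_c 17.700(4)
_cell_angle_alpha 90
_cell_angle_beta 90
_cell_angle_gamma 90
_symmetry_space_group_name_H-M 'P 21 21 21'
loop_
_symmetry_equiv_pos_as_xyz
'x,y,z'
'-x+1/2,-y,z+1/2'
'x+1/2,-y+1/2,-z'
'-x,y+1/2,-z+1/2'
loop_
_atom_site_label
_atom_site_type_symbol
_atom_site_fract_x
_atom_site_fract_y
_atom_site_fract_z
_atom_site_occupancy
_atom_site_U_iso_or_equiv
C1 C 0.1234 0.2345 0.0456 1.0 0.025
C2 C 0.3456 0.1234 0.1234 1.0 0.030
O1 O 0.2222 0.4444 0.0789 1.0 0.028
H1 H 0.1000 0.3000 0.1500 1.0 0.040
loop_
_atom_site_aniso_label
_atom_site_aniso_U_11
_atom_site_aniso_U_22
_atom_site_aniso_U_33
_atom_site_aniso_U_23
_atom_site_aniso_U_13
_atom_site_aniso_U_12
C1 0.020 0.030 0.025 0.002 -0.001 0.003
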