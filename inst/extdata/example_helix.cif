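data_example_helix
_entry.id 'example_helix'

_cell.entry_id 'example_helix'
_cell.length_a 1
_cell.length_b 1
_cell.length_c 1
_cell.angle_alpha 90
_cell.angle_beta 90
_cell.angle_gamma 90

_symmetry.entry_id 'example_helix'
_symmetry.space_group_name_H-M ''

loop_
_entity.id
_entity.type
1 polymer

loop_
_entity_poly.entity_id
_entity_poly.type
_entity_poly.pdbx_strand_id
_entity_poly.pdbx_seq_one_letter_code
1 polypeptide(L) A ?



loop_
_chem_comp.id
_chem_comp.type
ALA .
ASP .
CYS .
GLU .
GLY .
HIS .
LEU .
LYS .
MET .
PHE .
TRP .
VAL .

loop_
_exptl.entry_id
_exptl.method
'example_helix' 'X-RAY DIFFRACTION'

loop_
_struct_asym.id
_struct_asym.entity_id
Axp 1



loop_
_atom_type.symbol
C
N
O
S


loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_formal_charge
_atom_site.auth_atom_id
_atom_site.auth_comp_id
_atom_site.auth_seq_id
_atom_site.auth_asym_id
_atom_site.pdbx_PDB_model_num
ATOM 1 N N . ALA Axp 1 . ? 0 0 0 1 0 ? N ALA 1 A 1
ATOM 2 C CA . ALA Axp 1 . ? 1.458 0 0 1 0 ? CA ALA 1 A 1
ATOM 3 C C . ALA Axp 1 . ? 2.009 1.422 0 1 0 ? C ALA 1 A 1
ATOM 4 O O . ALA Axp 1 . ? 2.91 1.749 -0.773 1 0 ? O ALA 1 A 1
ATOM 5 C CB . ALA Axp 1 . ? 1.968 -0.721 1.249 1 0 ? CB ALA 1 A 1
ATOM 6 N N . VAL Axp 1 . ? 1.463 2.263 0.872 1 0 ? N VAL 2 A 1
ATOM 7 C CA . VAL Axp 1 . ? 1.899 3.65 0.974 1 0 ? CA VAL 2 A 1
ATOM 8 C C . VAL Axp 1 . ? 1.768 4.37 -0.364 1 0 ? C VAL 2 A 1
ATOM 9 O O . VAL Axp 1 . ? 2.689 5.059 -0.802 1 0 ? O VAL 2 A 1
ATOM 10 C CB . VAL Axp 1 . ? 1.039 4.379 2.007 1 0 ? CB VAL 2 A 1
ATOM 11 C CG1 . VAL Axp 1 . ? 1.495 5.836 2.115 1 0 ? CG1 VAL 2 A 1
ATOM 12 C CG2 . VAL Axp 1 . ? 1.186 3.697 3.367 1 0 ? CG2 VAL 2 A 1
ATOM 13 N N . LEU Axp 1 . ? 0.618 4.205 -1.008 1 0 ? N LEU 3 A 1
ATOM 14 C CA . LEU Axp 1 . ? 0.364 4.838 -2.297 1 0 ? CA LEU 3 A 1
ATOM 15 C C . LEU Axp 1 . ? 1.421 4.443 -3.323 1 0 ? C LEU 3 A 1
ATOM 16 O O . LEU Axp 1 . ? 1.961 5.294 -4.03 1 0 ? O LEU 3 A 1
ATOM 17 C CB . LEU Axp 1 . ? -1.006 4.402 -2.816 1 0 ? CB LEU 3 A 1
ATOM 18 C CG . LEU Axp 1 . ? -1.274 5.065 -4.169 1 0 ? CG LEU 3 A 1
ATOM 19 C CD1 . LEU Axp 1 . ? -2.646 4.628 -4.689 1 0 ? CD1 LEU 3 A 1
ATOM 20 C CD2 . LEU Axp 1 . ? -0.194 4.646 -5.166 1 0 ? CD2 LEU 3 A 1
ATOM 21 N N . LYS Axp 1 . ? 1.711 3.149 -3.398 1 0 ? N LYS 4 A 1
ATOM 22 C CA . LYS Axp 1 . ? 2.704 2.639 -4.337 1 0 ? CA LYS 4 A 1
ATOM 23 C C . LYS Axp 1 . ? 4.057 3.309 -4.126 1 0 ? C LYS 4 A 1
ATOM 24 O O . LYS Axp 1 . ? 4.701 3.745 -5.081 1 0 ? O LYS 4 A 1
ATOM 25 C CB . LYS Axp 1 . ? 2.869 1.132 -4.135 1 0 ? CB LYS 4 A 1
ATOM 26 C CG . LYS Axp 1 . ? 3.912 0.598 -5.121 1 0 ? CG LYS 4 A 1
ATOM 27 C CD . LYS Axp 1 . ? 4.078 -0.911 -4.92 1 0 ? CD LYS 4 A 1
ATOM 28 C CE . LYS Axp 1 . ? 5.119 -1.445 -5.904 1 0 ? CE LYS 4 A 1
ATOM 29 N NZ . LYS Axp 1 . ? 5.279 -2.893 -5.712 1 0 ? NZ LYS 4 A 1
ATOM 30 N N . ASP Axp 1 . ? 4.484 3.388 -2.87 1 0 ? N ASP 5 A 1
ATOM 31 C CA . ASP Axp 1 . ? 5.761 4.005 -2.531 1 0 ? CA ASP 5 A 1
ATOM 32 C C . ASP Axp 1 . ? 5.83 5.442 -3.035 1 0 ? C ASP 5 A 1
ATOM 33 O O . ASP Axp 1 . ? 6.82 5.851 -3.64 1 0 ? O ASP 5 A 1
ATOM 34 C CB . ASP Axp 1 . ? 5.938 4.011 -1.011 1 0 ? CB ASP 5 A 1
ATOM 35 C CG . ASP Axp 1 . ? 7.258 4.648 -0.662 1 0 ? CG ASP 5 A 1
ATOM 36 O OD1 . ASP Axp 1 . ? 7.591 4.752 0.495 1 0 ? OD1 ASP 5 A 1
ATOM 37 O OD2 . ASP Axp 1 . ? 8.064 5.1 -1.635 1 0 ? OD2 ASP 5 A 1
ATOM 38 N N . GLU Axp 1 . ? 4.771 6.204 -2.781 1 0 ? N GLU 6 A 1
ATOM 39 C CA . GLU Axp 1 . ? 4.709 7.597 -3.208 1 0 ? CA GLU 6 A 1
ATOM 40 C C . GLU Axp 1 . ? 4.899 7.721 -4.716 1 0 ? C GLU 6 A 1
ATOM 41 O O . GLU Axp 1 . ? 5.674 8.553 -5.187 1 0 ? O GLU 6 A 1
ATOM 42 C CB . GLU Axp 1 . ? 3.345 8.184 -2.839 1 0 ? CB GLU 6 A 1
ATOM 43 C CG . GLU Axp 1 . ? 3.282 9.646 -3.288 1 0 ? CG GLU 6 A 1
ATOM 44 C CD . GLU Axp 1 . ? 1.938 10.224 -2.925 1 0 ? CD GLU 6 A 1
ATOM 45 O OE1 . GLU Axp 1 . ? 1.683 11.375 -3.194 1 0 ? OE1 GLU 6 A 1
ATOM 46 O OE2 . GLU Axp 1 . ? 1.024 9.462 -2.304 1 0 ? OE2 GLU 6 A 1
ATOM 47 N N . CYS Axp 1 . ? 4.187 6.887 -5.467 1 0 ? N CYS 7 A 1
ATOM 48 C CA . CYS Axp 1 . ? 4.276 6.902 -6.922 1 0 ? CA CYS 7 A 1
ATOM 49 C C . CYS Axp 1 . ? 5.712 6.685 -7.389 1 0 ? C CYS 7 A 1
ATOM 50 O O . CYS Axp 1 . ? 6.209 7.406 -8.254 1 0 ? O CYS 7 A 1
ATOM 51 C CB . CYS Axp 1 . ? 3.403 5.787 -7.498 1 0 ? CB CYS 7 A 1
ATOM 52 S SG . CYS Axp 1 . ? 3.514 5.805 -9.308 1 0 ? SG CYS 7 A 1
ATOM 53 N N . PHE Axp 1 . ? 6.372 5.687 -6.812 1 0 ? N PHE 8 A 1
ATOM 54 C CA . PHE Axp 1 . ? 7.751 5.373 -7.167 1 0 ? CA PHE 8 A 1
ATOM 55 C C . PHE Axp 1 . ? 8.66 6.581 -6.968 1 0 ? C PHE 8 A 1
ATOM 56 O O . PHE Axp 1 . ? 9.464 6.915 -7.839 1 0 ? O PHE 8 A 1
ATOM 57 C CB . PHE Axp 1 . ? 8.257 4.229 -6.287 1 0 ? CB PHE 8 A 1
ATOM 58 C CG . PHE Axp 1 . ? 9.68 3.905 -6.654 1 0 ? CG PHE 8 A 1
ATOM 59 C CD1 . PHE Axp 1 . ? 10.354 2.898 -5.989 1 0 ? CD1 PHE 8 A 1
ATOM 60 C CD2 . PHE Axp 1 . ? 10.317 4.618 -7.653 1 0 ? CD2 PHE 8 A 1
ATOM 61 C CE1 . PHE Axp 1 . ? 11.661 2.601 -6.326 1 0 ? CE1 PHE 8 A 1
ATOM 62 C CE2 . PHE Axp 1 . ? 11.623 4.318 -7.991 1 0 ? CE2 PHE 8 A 1
ATOM 63 C CZ . PHE Axp 1 . ? 12.295 3.31 -7.326 1 0 ? CZ PHE 8 A 1
ATOM 64 N N . GLY Axp 1 . ? 8.528 7.232 -5.817 1 0 ? N GLY 9 A 1
ATOM 65 C CA . GLY Axp 1 . ? 9.336 8.403 -5.502 1 0 ? CA GLY 9 A 1
ATOM 66 C C . GLY Axp 1 . ? 9.171 9.489 -6.56 1 0 ? C GLY 9 A 1
ATOM 67 O O . GLY Axp 1 . ? 10.153 10.06 -7.036 1 0 ? O GLY 9 A 1
ATOM 68 N N . HIS Axp 1 . ? 7.924 9.768 -6.925 1 0 ? N HIS 10 A 1
ATOM 69 C CA . HIS Axp 1 . ? 7.629 10.785 -7.927 1 0 ? CA HIS 10 A 1
ATOM 70 C C . HIS Axp 1 . ? 8.339 10.485 -9.243 1 0 ? C HIS 10 A 1
ATOM 71 O O . HIS Axp 1 . ? 8.957 11.366 -9.841 1 0 ? O HIS 10 A 1
ATOM 72 C CB . HIS Axp 1 . ? 6.118 10.904 -8.165 1 0 ? CB HIS 10 A 1
ATOM 73 C CG . HIS Axp 1 . ? 5.764 11.947 -9.198 1 0 ? CG HIS 10 A 1
ATOM 74 N ND1 . HIS Axp 1 . ? 4.472 12.175 -9.522 1 0 ? ND1 HIS 10 A 1
ATOM 75 C CD2 . HIS Axp 1 . ? 6.559 12.752 -9.912 1 0 ? CD2 HIS 10 A 1
ATOM 76 C CE1 . HIS Axp 1 . ? 4.447 13.136 -10.452 1 0 ? CE1 HIS 10 A 1
ATOM 77 N NE2 . HIS Axp 1 . ? 5.711 13.495 -10.698 1 0 ? NE2 HIS 10 A 1
ATOM 78 N N . TRP Axp 1 . ? 8.247 9.236 -9.688 1 0 ? N TRP 11 A 1
ATOM 79 C CA . TRP Axp 1 . ? 8.881 8.818 -10.933 1 0 ? CA TRP 11 A 1
ATOM 80 C C . TRP Axp 1 . ? 10.381 9.091 -10.908 1 0 ? C TRP 11 A 1
ATOM 81 O O . TRP Axp 1 . ? 10.939 9.635 -11.861 1 0 ? O TRP 11 A 1
ATOM 82 C CB . TRP Axp 1 . ? 8.662 7.319 -11.139 1 0 ? CB TRP 11 A 1
ATOM 83 C CG . TRP Axp 1 . ? 9.317 6.889 -12.426 1 0 ? CG TRP 11 A 1
ATOM 84 C CD1 . TRP Axp 1 . ? 9.335 5.648 -12.937 1 0 ? CD1 TRP 11 A 1
ATOM 85 C CD2 . TRP Axp 1 . ? 10.061 7.744 -13.353 1 0 ? CD2 TRP 11 A 1
ATOM 86 N NE1 . TRP Axp 1 . ? 10.025 5.64 -14.119 1 0 ? NE1 TRP 11 A 1
ATOM 87 C CE2 . TRP Axp 1 . ? 10.481 6.907 -14.403 1 0 ? CE2 TRP 11 A 1
ATOM 88 C CE3 . TRP Axp 1 . ? 10.379 9.103 -13.377 1 0 ? CE3 TRP 11 A 1
ATOM 89 C CZ2 . TRP Axp 1 . ? 11.219 7.447 -15.451 1 0 ? CZ2 TRP 11 A 1
ATOM 90 C CZ3 . TRP Axp 1 . ? 11.105 9.612 -14.416 1 0 ? CZ3 TRP 11 A 1
ATOM 91 C CH2 . TRP Axp 1 . ? 11.525 8.79 -15.452 1 0 ? CH2 TRP 11 A 1
ATOM 92 N N . MET Axp 1 . ? 11.028 8.711 -9.811 1 0 ? N MET 12 A 1
ATOM 93 C CA . MET Axp 1 . ? 12.464 8.914 -9.659 1 0 ? CA MET 12 A 1
ATOM 94 C C . MET Axp 1 . ? 12.832 10.386 -9.813 1 0 ? C MET 12 A 1
ATOM 95 O O . MET Axp 1 . ? 13.773 10.729 -10.528 1 0 ? O MET 12 A 1
ATOM 96 C CB . MET Axp 1 . ? 12.9 8.443 -8.271 1 0 ? CB MET 12 A 1
ATOM 97 C CG . MET Axp 1 . ? 14.405 8.655 -8.11 1 0 ? CG MET 12 A 1
ATOM 98 S SD . MET Axp 1 . ? 14.922 8.096 -6.463 1 0 ? SD MET 12 A 1
ATOM 99 C CE . MET Axp 1 . ? 16.697 8.456 -6.55 1 0 ? CE MET 12 A 1

_refine.entry_id xxxx
_refine.ls_d_res_high 1.50
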