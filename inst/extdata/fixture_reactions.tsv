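# Bisulfite-formose free-energy map: reaction table.
# delta_g_printed = free-energy change printed in the running text (kcal/mol);
# blank when the text gives no number for this step. flag marks documented
# discrepancies between printed values and the G_rel arithmetic.
id	reactants	products	ts_id	category	delta_g_printed	flag	provenance	note
r_add_1O	1 + H2SO3	2	ts_add_1O	adduct_formation	-3.0		3.1	O-attack on formaldehyde
r_add_1S	1 + H2SO3	3	ts_add_1S	adduct_formation	2.6		3.1	S-attack on formaldehyde
r_add_4S	4 + H2SO3	5	ts_add_4S	adduct_formation			3.1	S-attack on glycolaldehyde; figure-only energetics
r_add_6i	4 + H2SO3	6	ts_add_6i	adduct_formation	2.0		3.1	hydroxyl O-attack at the carbonyl
r_add_6ii	4 + H2SO3	6	ts_add_6ii	adduct_formation	2.0		3.1	sulfoxide O-attack at the carbonyl
r_add_7	4 + H2SO3	7 + H2O	ts_add_7	adduct_formation	-1.3	printed_rounding	3.1	printed -1.3 vs G_rel arithmetic -1.4
r_shift_69	6	9	ts_shift_a	rearrangement			3.1	into the ring intermediate
r_shift_98	9	8	ts_shift_b	rearrangement			3.1	out of the ring intermediate
r_shift_68	6	8	ts_shift_sym	rearrangement	-2.6		3.1	direct bisulfite shift, symmetric TS
r_dehyd_8	8	7 + H2O	ts_hyd_7	dehydration	-0.8		3.1	reverse is hydration, barrier ~13
r_hyd_1	1 + H2O	10		other			3.2	formaldehyde hydration
r_can_c1	1 + 10	11 + 12	ts_can_c1	cannizzaro	-22.2		3.2	neutral-conditions Cannizzaro
r_can_c1b	1 + 2	11 + 13	ts_can_c1b	cannizzaro	-8.9		3.2	bisulfite adduct oxidized instead
r_xcan_i	1 + 4 + H2O	12 + 14	ts_xcan_i	cannizzaro	-16.3		3.2	cross-Cannizzaro, no sulfur
r_xcan_ii	1 + 7 + H2O	12 + 15	ts_xcan_ii	cannizzaro			3.2	bisulfite spectator on the C2 reactant
r_xcan_iii	2 + 4	13 + 14	ts_xcan_iii	cannizzaro	-3.1		3.2	bisulfite on the oxidized C1
r_xcan_iv	2 + 7	13 + 15		cannizzaro	-5.2		3.2	bisulfite on both reactants
r_enol_7	7	7ec	ts_enol_7	enolization			3.3	barrier +27.5
r_enol_7t	7	7et	ts_enol_7t	enolization			3.3	trans-enol, less favoured
r_enol_4	4	4ec	ts_enol_4	enolization			3.3	non-sulfur enolization
r_enol_4t	4	4et		enolization			3.5
r_aldol_7ec16	7ec + 1 + H2O	16 + H2SO3	ts_aldol_16	aldol			3.3	intramolecular catalysis, SO2 eliminated
r_aldol_7ec17	7ec + 1	17	ts_aldol_17	aldol			3.3	bisulfite retained; text reports overall dG -4.6, barrier +32.1 from aldehydic reactants
r_aldol_4ec16	4ec + 1	16	ts_aldol_4	aldol			3.3	non-sulfur analog
r_add_16	16 + H2SO3	17 + H2O		adduct_formation	0.7		3.3	barrier ~2, imputed in kinetics
r_shift_1718	17	18		rearrangement			3.4	via SO2 removal/re-addition
r_enol_17c	17	17ec		enolization			3.4
r_enol_17t	17	17et		enolization			3.4
r_enol_18c	18	18ec		enolization			3.4
r_enol_18t	18	18et		enolization			3.4
r_taut_1719	17	19		tautomerization			3.4	towards the triose sink
r_enol_19	19	19e		enolization			3.4
r_aldol_1720	17 + 1 + H2O	20 + H2SO3	ts_aldol_1720	aldol	-12.6		3.4	printed as -27.4 - (-17.4 + 2.6)
r_aldol_1721	17 + 1	21	ts_aldol_1721	aldol	-7.3	printed_arithmetic_discrepancy	3.4	printed -21.8 - (-17.4 + 2.6) = -7.3 but operands give -7.0
r_aldol_1822	18 + 1	22	ts_aldol_1822	aldol			3.4	parasitic dead-end
r_aldol_1823	18 + 1	23	ts_aldol_1823	aldol	-12.7		3.4
r_aldol_1724	17 + 1	24	ts_aldol_1724	aldol	-11.9		3.4
r_add_20_23	20 + H2SO3	23 + H2O		adduct_formation			3.4
r_add_20_24	20 + H2SO3	24 + H2O		adduct_formation			3.4
r_add_20_25	20 + H2SO3	25 + H2O		adduct_formation			3.4	no direct aldol route to 25
r_aldol_1620	16 + 1	20	ts_aldol_1620	aldol			3.4	non-sulfur C3+C1 aldol
r_enol_24c	24	24ec	ts_enol_24c	enolization			3.5	barrier +21.5
r_enol_24t	24	24et	ts_enol_24t	enolization			3.5	barrier +21.5
r_taut_ery	24ec	26ery	ts_taut_ery	tautomerization			3.5
r_taut_thr	24et	26thr	ts_taut_thr	tautomerization			3.5
r_retro_thr	26thr + H2O	4 + 4ec + H2SO3	ts_retro_thr	retro_aldol	2.5		3.5	bisulfite eliminated; barrier +18.6
r_retro_ery	26ery + H2O	4 + 4et + H2SO3	ts_retro_ery	retro_aldol	3.3		3.5	bisulfite eliminated; barrier +20.3
r_retro_27	27thr	4 + 7		retro_aldol			3.5	marginally exergonic; barrier expected high
r_retro_28	28thr	4 + 7		retro_aldol			3.5	marginally endergonic; barrier expected high
r_add_29_26	29thr + H2SO3	26thr + H2O		adduct_formation			3.5
r_add_29_27	29thr + H2SO3	27thr + H2O		adduct_formation			3.5
r_add_29_28	29thr + H2SO3	28thr + H2O		adduct_formation			3.5
r_taut_2029	20	29thr	ts_taut_2029	tautomerization			3.5	non-sulfur ketose-aldose
r_retro_29thr	29thr	4 + 4ec	ts_retro_29	retro_aldol			3.5	overall dG +2.9 post-tautomerization per text
r_aldol_30rib	7 + 17 + H2O	30rib + H2SO3		aldol			3.6	C2+C3 aldol, 2,4-adduct
r_aldol_30ara	7 + 17 + H2O	30ara + H2SO3		aldol			3.6
r_aldol_30xyl	7 + 17 + H2O	30xyl + H2SO3		aldol			3.6
r_aldol_30lyx	7 + 17 + H2O	30lyx + H2SO3		aldol			3.6	slightly downhill per text
r_ring_31rib	30rib	31rib		ring_closure			3.6	pyranose
r_ring_31ara	30ara	31ara		ring_closure			3.6
r_ring_31xyl	30xyl	31xyl		ring_closure			3.6
r_ring_31lyx	30lyx	31lyx		ring_closure			3.6
r_aldol_32rib	7 + 18 + H2O	32rib + H2SO3		aldol			3.6	C2+C3 aldol, 2,5-adduct
r_aldol_32ara	7 + 18 + H2O	32ara + H2SO3		aldol			3.6
r_aldol_32xyl	7 + 18 + H2O	32xyl + H2SO3		aldol			3.6	slightly exergonic per text
r_aldol_32lyx	7 + 18 + H2O	32lyx + H2SO3		aldol			3.6
r_ring_33rib	32rib	33rib		ring_closure			3.6	furanose
r_ring_33ara	32ara	33ara		ring_closure			3.6
r_ring_33xyl	32xyl	33xyl		ring_closure			3.6
r_ring_33lyx	32lyx	33lyx		ring_closure			3.6
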