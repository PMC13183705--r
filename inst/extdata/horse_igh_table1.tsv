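sample_id	n_raw	n_preproc	n_quality	n_annotated	n_unique	n_detected	n_filtered
horse1	94501	91830	38430	38430	33984	5158	2653
horse2	222339	216902	75118	75118	62435	7379	3730
horse3	452715	444022	202685	202685	132912	16012	8042
horse4	133538	131481	57447	57447	51791	6741	3141
horse5	210964	203754	89070	89070	65152	11612	6493
horse6	288611	278484	111060	111060	73434	11591	6035
horse7	408483	341226	26064	26064	18078	2794	1342
horse8	481150	456456	154359	154359	103354	8869	3780
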