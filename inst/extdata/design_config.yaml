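# Declarative design matrix of the heterocyclic fragment collection.
#
# Seven series of vicinally disubstituted saturated rings. Ring position 1 is
# the anchor atom (N for pyrrolidine/piperidine, S for the cyclic sulfone, the
# CF2 carbon for gem-difluorocyclohexane); head_position carries the polar
# head group unmasked from the directing group, aryl_position the aryl group
# installed vicinal to it. Each series expands over head x relative
# configuration x aryl (in that nesting order); the fragments list assigns the
# editorial FRAG numbering and synthesis status to that expansion order.
#
# Status values: synthesized | not_prepared | commercial.

library_name: stereodefined heterocyclic fragment collection
series:

  - name: 2,3-pyrrolidine
    scaffold: pyrrolidine
    head_position: 2
    aryl_position: 3
    aryls: [4-methoxyphenyl, 4-fluorophenyl]
    heads: [carboxylic_acid, primary_amide, primary_alcohol]
    configs: [cis]
    fragments:
      - {frag_id: FRAG1}
      - {frag_id: FRAG2}
      - {frag_id: FRAG3}
      - {frag_id: FRAG4}
      - {frag_id: FRAG5}
      - {frag_id: FRAG6}

  - name: 2,3-piperidine
    scaffold: piperidine
    head_position: 2
    aryl_position: 3
    aryls: [4-methoxyphenyl]
    heads: [primary_amide]
    configs: [cis]
    fragments:
      - {frag_id: FRAG7}

  - name: 3,4-pyrrolidine
    scaffold: pyrrolidine
    head_position: 3
    aryl_position: 4
    aryls: [4-methoxyphenyl, 4-fluorophenyl]
    heads: [carboxylic_acid, primary_amide, primary_alcohol]
    configs: [cis, trans]
    fragments:
      - {frag_id: FRAG8}
      - {frag_id: FRAG9}
      - {frag_id: FRAG10}
      - {frag_id: FRAG11}
      - {frag_id: FRAG12, status: not_prepared,
         status_reason: oxidative directing-group removal incompatible with the
           4-methoxyphenyl group (spirocyclization)}
      - {frag_id: FRAG13}
      - {frag_id: FRAG14}
      - {frag_id: FRAG15}
      - {frag_id: FRAG16}
      - {frag_id: FRAG17}
      - {frag_id: FRAG18}
      - {frag_id: FRAG19}

  - name: 3,4-piperidine
    scaffold: piperidine
    head_position: 3
    aryl_position: 4
    aryls: [4-methoxyphenyl, 4-fluorophenyl]
    heads: [carboxylic_acid, primary_amide, primary_alcohol]
    configs: [cis, trans]
    fragments:
      - {frag_id: FRAG20}
      - {frag_id: FRAG21, status: not_prepared,
         status_reason: cis-fluoroarene arylation gave inseparable cis/trans
           mixtures, epimerized fully to the trans analogue instead}
      - {frag_id: FRAG22}
      - {frag_id: FRAG23}
      - {frag_id: FRAG24, status: not_prepared,
         status_reason: oxidative directing-group removal incompatible with the
           4-methoxyphenyl group (spirocyclization)}
      - {frag_id: FRAG25, status: not_prepared,
         status_reason: cis-fluoroarene arylation gave inseparable cis/trans
           mixtures, epimerized fully to the trans analogue instead}
      - {frag_id: FRAG26, status: not_prepared,
         status_reason: oxidative directing-group removal incompatible with the
           4-methoxyphenyl group (spirocyclization)}
      - {frag_id: FRAG27}
      - {frag_id: FRAG28}
      - {frag_id: FRAG29, status: commercial,
         status_reason: paroxetine substructure, commercially available}
      - {frag_id: FRAG30}
      - {frag_id: FRAG31, status: commercial,
         status_reason: paroxetine substructure, commercially available}

  - name: 4,3-piperidine
    scaffold: piperidine
    head_position: 4
    aryl_position: 3
    aryls: [4-methoxyphenyl, 4-fluorophenyl]
    heads: [carboxylic_acid, primary_amide, primary_alcohol, nitrile]
    configs: [cis, trans]
    head_configs:
      nitrile: [cis]
    fragments:
      - {frag_id: FRAG32}
      - {frag_id: FRAG33}
      - {frag_id: FRAG34}
      - {frag_id: FRAG35}
      - {frag_id: FRAG36}
      - {frag_id: FRAG37}
      - {frag_id: FRAG38}
      - {frag_id: FRAG39}
      - {frag_id: FRAG40}
      - {frag_id: FRAG41}
      - {frag_id: FRAG42}
      - {frag_id: FRAG43}
      - {frag_id: FRAG44}
      - {frag_id: FRAG45}

  - name: 4,3-cyclic-sulfone
    scaffold: cyclic_sulfone_6
    head_position: 4
    aryl_position: 3
    aryls: [4-methoxyphenyl]
    heads: [carboxylic_acid, primary_alcohol]
    configs: [cis]
    fragments:
      - {frag_id: FRAG46}
      - {frag_id: FRAG47}

  - name: 4,3-gem-difluorocyclohexane
    scaffold: gem_difluorocyclohexane
    head_position: 4
    aryl_position: 3
    aryls: [4-methoxyphenyl]
    heads: [carboxylic_acid, primary_alcohol]
    configs: [cis, trans]
    fragments:
      - {frag_id: FRAG48}
      - {frag_id: FRAG49}
      - {frag_id: FRAG50}
      - {frag_id: FRAG51}
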