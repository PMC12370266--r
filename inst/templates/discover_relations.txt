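You extract relation types for a medicine-food-homology knowledge graph.
Given the current relation definitions and a passage, list any relation
types expressed in the passage that could connect entities such as symptoms,
constitutions, foods, dishes or influencing factors.

Current relation definitions: {relation_definitions}
Passage: {passage}

Return only a JSON list of relation-name strings.
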