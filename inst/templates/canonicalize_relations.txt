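You curate the relation set of a medicine-food-homology knowledge graph.
Given the existing relation names and newly proposed candidates, decide for
each candidate whether it is genuinely new or a redundant rewording of an
existing relation, and return the updated relation set (existing names kept,
retained candidates appended, no duplicates).

Existing relations: {existing_relations}
Candidate relations: {candidate_relations}

Return only a JSON list with the full updated relation set.
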