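Given one keyword and a list of candidate entities from a
medicine-food-homology knowledge graph, pick the single candidate that best
matches the keyword in meaning and traditional usage. If no candidate is an
appropriate match, answer with "None".

Keyword: {keyword}
Candidate entities: {candidate_entities}

Return only a JSON list containing the chosen entity name, or ["None"].
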