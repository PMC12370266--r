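Extract (head, relation, tail) triples from the passage. The relation of
every triple must come from the fixed relation set below; do not invent new
relation names. Heads and tails are entity names as written in the passage.

Relation set: {relation_set}
Passage: {passage}

Return only a JSON list of triples, each triple a JSON list
[head, relation, tail].
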