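Rewrite the passage below so it stands alone: resolve pronouns and elliptical
references using the document title and the neighboring passages, and drop
content that is irrelevant to medicine-food homology, TCM constitutions,
symptoms, foods or dishes. Preserve all factual content.

Document title: {title}
Neighboring passages: {neighbor_passages}
Passage: {passage}

Return only the rewritten passage text.
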