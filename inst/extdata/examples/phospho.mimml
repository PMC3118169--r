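<?xml version="1.0" encoding="UTF-8"?>
<Diagram xmlns="urn:mimml:1.0" width="360" height="160">
  <EntityGlyph visId="A" type="simple-physical-entity" label="A" centerX="260" centerY="80" width="70" height="28"/>
  <EntityGlyph visId="P" type="modifier" label="P" centerX="70" centerY="80" width="24" height="16"/>
  <EntityGlyph visId="phosA_cplx" type="explicit-complex" lineRef="phosA" linePosition="0.5"/>
  <InteractionGlyph visId="phosA" type="covalent-modification">
    <Point x="84" y="80" arrowHead="none" visRef="P"/>
    <Point x="225" y="80" arrowHead="barbed" visRef="A"/>
  </InteractionGlyph>
  <MimBio>
    <dc-creator>mimml examples</dc-creator>
    <dc-identifier>example-phospho</dc-identifier>
    <dc-title>Phosphorylation of A</dc-title>
  </MimBio>
</Diagram>
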