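<?xml version="1.0" encoding="UTF-8"?>
<Diagram xmlns="urn:mimml:1.0" width="420" height="220">
  <EntityGlyph visId="A" type="simple-physical-entity" label="A" centerX="70" centerY="110" width="70" height="28"/>
  <EntityGlyph visId="B" type="simple-physical-entity" label="B" centerX="340" centerY="60" width="70" height="28"/>
  <EntityGlyph visId="C" type="simple-physical-entity" label="C" centerX="340" centerY="160" width="70" height="28"/>
  <InteractionGlyph visId="convABC" type="stoichiometric-conversion">
    <Point x="105" y="110" arrowHead="none" visRef="A"/>
    <Point x="305" y="60" arrowHead="filled-triangle" visRef="B"/>
    <Branch position="0.5">
      <Point x="305" y="160" arrowHead="filled-triangle" visRef="C"/>
    </Branch>
  </InteractionGlyph>
  <MimBio>
    <dc-creator>mimml examples</dc-creator>
    <dc-identifier>example-conversion-branch</dc-identifier>
    <dc-title>Conversion of A to B and C</dc-title>
  </MimBio>
</Diagram>
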