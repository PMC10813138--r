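<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic three-drug example in the minimal Drugbank-style dialect
     read by parse_drugbank_xml(); authored for tests, transcribes no
     licensed database content. -->
<drugbank>
  <drug>
    <name>Metoprolol</name>
    <atc-codes>
      <atc-code code="C07AB02"/>
    </atc-codes>
    <enzymes>
      <enzyme>
        <name>CYP2D6</name>
        <actions>
          <action>substrate</action>
        </actions>
      </enzyme>
    </enzymes>
  </drug>
  <drug>
    <name>Omeprazole</name>
    <atc-codes>
      <atc-code code="A02BC01"/>
    </atc-codes>
    <enzymes>
      <enzyme>
        <name>CYP2C19</name>
        <actions>
          <action>substrate</action>
          <action>inhibitor</action>
        </actions>
      </enzyme>
      <enzyme>
        <name>CYP3A4</name>
        <actions>
          <action>substrate</action>
        </actions>
      </enzyme>
    </enzymes>
  </drug>
  <drug>
    <name>Ramipril</name>
    <atc-codes>
      <atc-code code="C09AA05"/>
    </atc-codes>
    <enzymes>
      <enzyme>
        <name>CYP2D6</name>
        <actions>
          <action>inhibitor</action>
        </actions>
      </enzyme>
    </enzymes>
  </drug>
</drugbank>
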