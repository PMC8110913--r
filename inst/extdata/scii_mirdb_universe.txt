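rno-let-7f-5p
rno-miR-105
rno-miR-1188-3p
rno-miR-125b-2-3p
rno-miR-125b-5p
rno-miR-127-3p
rno-miR-129-1-3p
rno-miR-129-2-3p
rno-miR-1298
rno-miR-1306-5p
rno-miR-130b-3p
rno-miR-132-5p
rno-miR-133a-5p
rno-miR-136-5p
rno-miR-140-5p
rno-miR-144-5p
rno-miR-146a-5p
rno-miR-148a-3p
rno-miR-149-5p
rno-miR-154-3p
rno-miR-155-3p
rno-miR-181b-5p
rno-miR-182
rno-miR-183-3p
rno-miR-1839-5p
rno-miR-185-3p
rno-miR-186-3p
rno-miR-199a-3p
rno-miR-19a-3p
rno-miR-19b-3p
rno-miR-200b-3p
rno-miR-201-5p
rno-miR-204-3p
rno-miR-20b-5p
rno-miR-21-5p
rno-miR-210-3p
rno-miR-214-3p
rno-miR-22-3p
rno-miR-28-5p
rno-miR-291a-3p
rno-miR-30c-5p
rno-miR-323-3p
rno-miR-323-5p
rno-miR-330-5p
rno-miR-336-5p
rno-miR-339-5p
rno-miR-346
rno-miR-34c-3p
rno-miR-352
rno-miR-3547
rno-miR-365-3p
rno-miR-369-5p
rno-miR-375-5p
rno-miR-376a-5p
rno-miR-376b-5p
rno-miR-377-5p
rno-miR-381-3p
rno-miR-463-3p
rno-miR-465-3p
rno-miR-466c-5p
rno-miR-466d
rno-miR-487b-3p
rno-miR-493-5p
rno-miR-497-5p
rno-miR-499-5p
rno-miR-505-5p
rno-miR-542-5p
rno-miR-632
rno-miR-665
rno-miR-672-3p
rno-miR-675-5p
rno-miR-743a-3p
rno-miR-743b-3p
rno-miR-760-5p
rno-miR-873-5p
rno-miR-935
rno-miR-98-5p
rno-miR-99a-3p
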